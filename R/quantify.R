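#' Band integration window
#'
#' A closed wavenumber interval with an optional local baseline rule:
#' `"none"` integrates the raw signal; `"linear_endpoints"` subtracts the
#' chord joining the two window-endpoint absorbances before integrating
#' (the usual local baseline for band-area comparison).
#'
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @param baseline `"none"` or `"linear_endpoints"`.
#' @return An object of class `band_window`.
#' @export
band_window <- function(lo, hi, baseline = c("none", "linear_endpoints")) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    abort_sm("band window must have finite lo < hi", "parameter")
  structure(list(lo = lo, hi = hi, baseline = match.arg(baseline)),
            class = "band_window")
}

#' Integrate a band area per pixel
#'
#' Trapezoidal integration of each spectrum over the axis points inside the
#' window (closed interval, native grid — no resampling). With
#' `baseline = "linear_endpoints"` the chord joining the window endpoints
#' is subtracted first, so the area is measured above the local baseline
#' (and may be negative).
#'
#' @param map A [spectral_map].
#' @param window A [band_window] overlapping the axis with >= 2 points.
#' @return An object of class `band_quantification`: the `window` and one
#'   area (`absorbance * cm^-1`) per retained pixel in `values`.
#' @export
integrate_band <- function(map, window) {
  stopifnot(inherits(map, "spectral_map"), inherits(window, "band_window"))
  idx <- axis_in_window(map$axis, window$lo, window$hi)
  if (length(idx) < 2)
    abort_sm(sprintf("window [%g, %g] covers %d axis point(s); need >= 2",
                     window$lo, window$hi, length(idx)), "window")
  w <- map$axis[idx]
  A <- map$absorbance[, idx, drop = FALSE]
  if (window$baseline == "linear_endpoints") {
    k <- length(idx)
    frac <- (w - w[1]) / (w[k] - w[1])
    chord <- outer(A[, 1], 1 - frac) + outer(A[, k], frac)
    A <- A - chord
  }
  values <- apply(A, 1, function(x) pracma::trapz(w, x))
  structure(list(window = window, values = as.numeric(values)),
            class = "band_quantification")
}

#' Peak-shift-aware integration window
#'
#' Accounts for subtle peak shifts between datasets: searches the
#' map-mean spectrum for its maximum within `nominal_center +/-
#' search_radius` and centers a window of the requested half-width on the
#' located peak. Exact ties are broken toward `nominal_center`, then toward
#' the lower wavenumber. The returned window never extends beyond the axis
#' (clipped if necessary).
#'
#' @param map A [spectral_map] of retained pixels.
#' @param nominal_center Literature band position, cm^-1.
#' @param half_width Half-width of the integration window, cm^-1.
#' @param search_radius Search radius around the nominal center, cm^-1.
#' @param baseline Baseline rule passed to the returned [band_window].
#' @return A [band_window] centered on the located peak.
#' @export
adjust_window <- function(map, nominal_center, half_width, search_radius,
                          baseline = "none") {
  stopifnot(inherits(map, "spectral_map"))
  idx <- axis_in_window(map$axis, nominal_center - search_radius,
                        nominal_center + search_radius)
  if (!length(idx))
    abort_sm(sprintf("search region %g +/- %g cm^-1 lies outside the axis",
                     nominal_center, search_radius), "window")
  m <- colMeans(map$absorbance[, idx, drop = FALSE])
  w <- map$axis[idx]
  cand <- which(m == max(m))
  if (length(cand) > 1) {                       # tie-break rules
    d <- abs(w[cand] - nominal_center)
    cand <- cand[d == min(d)]
    cand <- cand[which.min(w[cand])]
  }
  peak <- w[cand[1]]
  lo <- max(peak - half_width, map$axis[1])
  hi <- min(peak + half_width, map$axis[length(map$axis)])
  band_window(lo, hi, baseline)
}

#' Per-cluster mean spectra
#'
#' Arithmetic mean spectrum of each cluster, for visual inspection and
#' cluster characterization. Rows are ordered by cluster label.
#'
#' @param map A [spectral_map] of retained pixels.
#' @param labels A `cluster_assignment` (or integer vector) aligned with
#'   the map's rows.
#' @return Matrix `n_clusters x n_wavenumbers`; row names are the labels.
#' @export
cluster_mean_spectra <- function(map, labels) {
  stopifnot(inherits(map, "spectral_map"))
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else
    as.integer(labels)
  if (length(lab) != nrow(map$absorbance))
    abort_sm(sprintf("labels cover %d pixels but map has %d",
                     length(lab), nrow(map$absorbance)), "label")
  u <- sort(unique(lab))
  out <- t(vapply(u, function(l)
    colMeans(map$absorbance[lab == l, , drop = FALSE]),
    numeric(ncol(map$absorbance))))
  rownames(out) <- u
  out
}

#' Amide I secondary-structure band assignments
#'
#' The default class-to-window table maps amide I sub-regions to secondary
#' structure classes using standard literature assignments: alpha-helix
#' 1648-1660, beta-sheet 1620-1640 and 1670-1695, turns 1660-1670, other
#' (random coil / side chains) 1640-1648 cm^-1. Fully overridable: supply
#' a named list of `band_window` lists, or a YAML file mapping class names
#' to `lo:hi` window strings.
#'
#' @param bands Named list: class name -> list of [band_window]s.
#' @param amide_window Full amide I interval over which the local linear
#'   baseline is anchored. Default `c(1600, 1700)`.
#' @return An object of class `structure_coefficients`.
#' @export
structure_coefficients <- function(bands = NULL,
                                   amide_window = c(1600, 1700)) {
  if (is.null(bands)) {
    bands <- list(
      "alpha_helix" = list(band_window(1648, 1660)),
      "beta_sheet"  = list(band_window(1620, 1640), band_window(1670, 1695)),
      "turns"       = list(band_window(1660, 1670)),
      "other"       = list(band_window(1640, 1648)))
  }
  if (is.null(names(bands)) || anyDuplicated(names(bands)))
    abort_sm("structure classes must be uniquely named", "configuration")
  for (cls in names(bands)) {
    if (!length(bands[[cls]]) ||
        !all(vapply(bands[[cls]], inherits, logical(1), "band_window")))
      abort_sm(sprintf("class %s must hold at least one band_window", cls),
               "configuration")
  }
  structure(list(classes = names(bands), bands = bands,
                 amide_window = as.numeric(amide_window)),
            class = "structure_coefficients")
}

#' Read structure coefficients from a YAML config
#'
#' Layout: a mapping of class name to a list of `"lo:hi"` strings, plus an
#' optional `amide_window: [lo, hi]` entry.
#'
#' @param path YAML file path.
#' @return A [structure_coefficients].
#' @export
read_structure_coefficients <- function(path) {
  cfg <- yaml::read_yaml(path)
  amide <- if (!is.null(cfg$amide_window)) as.numeric(cfg$amide_window)
           else c(1600, 1700)
  cfg$amide_window <- NULL
  bands <- lapply(cfg, function(ws) lapply(ws, function(s) {
    p <- as.numeric(strsplit(as.character(s), ":")[[1]])
    if (length(p) != 2 || anyNA(p))
      abort_sm(sprintf("cannot parse band window %s (expected lo:hi)", s),
               "configuration")
    band_window(p[1], p[2])
  }))
  structure_coefficients(bands, amide)
}

#' Estimate secondary-structure fractions per pixel
#'
#' Band-area based estimation of protein secondary-structure composition
#' from amide I features, with no spectral decomposition or curve fitting.
#' Per pixel: the chord baseline anchored at the endpoints of the full
#' amide I window is subtracted, each class's bands are integrated on the
#' corrected spectrum, negative class areas are clamped to 0, and the
#' areas are normalized to fractions summing to 1. Pixels whose total
#' clamped area is zero get `NA` fractions and are flagged.
#'
#' Fractions are invariant to overall spectrum scaling, so they can be
#' computed on raw or normalized absorbance alike.
#'
#' @param map A [spectral_map] of retained pixels containing the amide I
#'   region.
#' @param coeffs A [structure_coefficients]; default standard assignments.
#' @return Data.frame: `pixel_index` (0-based over the map rows), one
#'   fraction column per class, and logical `undefined` for zero-signal
#'   pixels.
#' @export
estimate_secondary_structure <- function(map,
                                         coeffs = structure_coefficients()) {
  stopifnot(inherits(map, "spectral_map"),
            inherits(coeffs, "structure_coefficients"))
  all_bands <- unlist(coeffs$bands, recursive = FALSE)
  overlaps <- vapply(all_bands, function(b)
    length(axis_in_window(map$axis, b$lo, b$hi)) >= 2, logical(1))
  if (!any(overlaps))
    abort_sm("no structure coefficient band overlaps the axis", "configuration")
  amide_idx <- axis_in_window(map$axis, coeffs$amide_window[1],
                              coeffs$amide_window[2])
  if (length(amide_idx) < 2)
    abort_sm("amide I region absent from axis", "configuration")
  # chord baseline over the full amide I window, subtracted once per pixel
  w_am <- map$axis[amide_idx]
  k <- length(amide_idx)
  frac <- (w_am - w_am[1]) / (w_am[k] - w_am[1])
  A <- map$absorbance[, amide_idx, drop = FALSE]
  A <- A - (outer(A[, 1], 1 - frac) + outer(A[, k], frac))
  corrected <- spectral_map(A, w_am, sample_ids = map$sample_ids)
  areas <- vapply(coeffs$classes, function(cls) {
    per_band <- vapply(coeffs$bands[[cls]], function(b) {
      idx <- axis_in_window(corrected$axis, b$lo, b$hi)
      if (length(idx) < 2) return(numeric(nrow(A)))
      integrate_band(corrected, band_window(b$lo, b$hi, "none"))$values
    }, numeric(nrow(A)))
    if (is.null(dim(per_band))) per_band <- matrix(per_band, nrow = nrow(A))
    rowSums(per_band)
  }, numeric(nrow(A)))
  if (is.null(dim(areas))) areas <- matrix(areas, nrow = 1,
                                           dimnames = list(NULL, coeffs$classes))
  areas[areas < 0] <- 0
  tot <- rowSums(areas)
  fractions <- areas / tot          # rows with tot == 0 become NaN
  fractions[tot == 0, ] <- NA_real_
  out <- data.frame(pixel_index = seq_len(nrow(A)) - 1L)
  out <- cbind(out, as.data.frame(fractions))
  out$undefined <- tot == 0
  out
}

#' Long-format group values for plotting and statistics
#'
#' Joins a per-pixel band quantification with sample annotations into a
#' tidy (pixel, group, value) table ready for violin plots or downstream
#' statistical comparison. No statistics are computed here.
#'
#' @param quant A [band_quantification] from [integrate_band].
#' @param map The [spectral_map] the quantification was computed on
#'   (supplies per-pixel sample ids).
#' @param annotations Annotation data.frame with a `sample_name` column.
#' @param group_var Annotation variable to group by (e.g.
#'   `"sample_name"`, `"condition"`).
#' @return Data.frame with columns `pixel_index`, `group`, `value`.
#' @export
group_values <- function(quant, map, annotations, group_var) {
  stopifnot(inherits(quant, "band_quantification"),
            inherits(map, "spectral_map"))
  if (!group_var %in% names(annotations))
    abort_sm(sprintf("variable %s not present in annotations", group_var),
             "annotation")
  if (length(quant$values) != nrow(map$absorbance))
    abort_sm("quantification and map cover different pixel counts", "label")
  if (!length(quant$values))
    return(data.frame(pixel_index = integer(), group = character(),
                      value = numeric()))
  idx <- match(map$sample_ids, annotations$sample_name)
  if (anyNA(idx))
    abort_sm(sprintf("sample(s) absent from annotations: %s",
                     paste(unique(map$sample_ids[is.na(idx)]), collapse = ", ")),
             "annotation")
  data.frame(pixel_index = seq_along(quant$values) - 1L,
             group = as.character(annotations[[group_var]][idx]),
             value = quant$values)
}
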