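#' Pre-processing parameters
#'
#' Bundles every tunable of the QC and pre-processing stage. All windows are
#' closed wavenumber intervals in cm^-1.
#'
#' @param empty_window Window over which mean absorbance identifies empty
#'   positions (holes, off-sample regions). Default `c(1600, 1700)`, the
#'   amide I region: any tissue pixel carries protein signal there.
#' @param empty_threshold Mean absorbance below which a pixel is called
#'   empty. Default `0.1`.
#' @param scatter_silent_window Spectroscopically silent region used to
#'   assess baseline slope. Default `c(1800, 2600)`: biological samples have
#'   essentially no fundamental vibrations there, so any pronounced slope is
#'   a scattering (Mie-type) baseline artefact.
#' @param scatter_slope_threshold Absolute least-squares slope
#'   (absorbance per cm^-1) in the silent window above which a pixel is
#'   flagged as scatter. Default `1e-3`.
#' @param scatter_negative_fraction_threshold Fraction of negative
#'   absorbance values across the full spectrum above which a pixel is
#'   flagged as scatter. Default `0.6`: noise-only empty spectra hover near
#'   0.5 and are the empty detector's concern; a clear majority of negative
#'   channels indicates a distorted, scattering-dominated baseline.
#' @param co2_window Atmospheric CO2 asymmetric-stretch region excised by
#'   [exclude_co2]. Default `c(2300, 2400)`.
#' @param sg_window_pts Savitzky-Golay window length in points (odd, >= 5).
#'   Default `9`.
#' @param sg_polyorder Savitzky-Golay polynomial order (>= 2,
#'   < `sg_window_pts`). Default `3`.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(empty_window = c(1600, 1700),
                              empty_threshold = 0.1,
                              scatter_silent_window = c(1800, 2600),
                              scatter_slope_threshold = 1e-3,
                              scatter_negative_fraction_threshold = 0.6,
                              co2_window = c(2300, 2400),
                              sg_window_pts = 9L,
                              sg_polyorder = 3L) {
  chk_window <- function(w, name) {
    if (length(w) != 2 || !all(is.finite(w)) || w[1] >= w[2])
      abort_sm(sprintf("%s must be a finite interval with lower < upper", name),
               "parameter")
  }
  chk_window(empty_window, "empty_window")
  chk_window(scatter_silent_window, "scatter_silent_window")
  chk_window(co2_window, "co2_window")
  if (empty_threshold < 0 || scatter_slope_threshold < 0)
    abort_sm("thresholds must be >= 0", "parameter")
  if (scatter_negative_fraction_threshold < 0 ||
      scatter_negative_fraction_threshold > 1)
    abort_sm("scatter_negative_fraction_threshold must be in [0, 1]", "parameter")
  sg_window_pts <- as.integer(sg_window_pts)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window_pts < 5L || sg_window_pts %% 2L == 0L)
    abort_sm("sg_window_pts must be an odd integer >= 5", "parameter")
  if (sg_polyorder < 2L || sg_polyorder >= sg_window_pts)
    abort_sm("sg_polyorder must be in [2, sg_window_pts - 1]", "parameter")
  structure(list(empty_window = as.numeric(empty_window),
                 empty_threshold = empty_threshold,
                 scatter_silent_window = as.numeric(scatter_silent_window),
                 scatter_slope_threshold = scatter_slope_threshold,
                 scatter_negative_fraction_threshold =
                   scatter_negative_fraction_threshold,
                 co2_window = as.numeric(co2_window),
                 sg_window_pts = sg_window_pts,
                 sg_polyorder = sg_polyorder),
            class = "preprocess_params")
}

#' QC mask constructor
#'
#' Per-pixel keep/exclude flags over the ORIGINAL pixel order, with a reason
#' code for every excluded pixel. Saved exclusion positions are what later
#' allows [repopulate] to restore results to acquisition layout.
#'
#' @param keep Logical vector, one entry per original pixel.
#' @param reason Character vector of reason codes (`"empty"`, `"scatter"`,
#'   `"manual"`), `NA` for kept pixels.
#' @return An object of class `qc_mask` with fields `keep`, `reason`,
#'   `original_n`.
#' @export
qc_mask <- function(keep, reason = NULL) {
  keep <- as.logical(keep)
  if (anyNA(keep)) abort_sm("keep flags must be TRUE/FALSE", "mask")
  if (is.null(reason)) reason <- ifelse(keep, NA_character_, "manual")
  reason <- as.character(reason)
  if (length(reason) != length(keep))
    abort_sm("reason must have one entry per pixel", "mask")
  if (any(!keep & is.na(reason)))
    abort_sm("every excluded pixel needs a reason code", "mask")
  reason[keep] <- NA_character_
  structure(list(keep = keep, reason = reason, original_n = length(keep)),
            class = "qc_mask")
}

#' @export
print.qc_mask <- function(x, ...) {
  cat(sprintf("<qc_mask> %d pixels, %d excluded", x$original_n, sum(!x$keep)))
  if (any(!x$keep)) {
    tab <- table(x$reason[!x$keep])
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Combine QC masks
#'
#' AND-combines the keep flags of two or more masks over the same original
#' pixels. Where several masks exclude the same pixel the first-listed
#' mask's reason code wins (a deterministic, order-stated rule).
#'
#' @param ... Two or more `qc_mask` objects with equal `original_n`.
#' @return A combined `qc_mask`.
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) && !inherits(masks[[1]], "qc_mask"))
    masks <- masks[[1]]
  stopifnot(length(masks) >= 1, all(vapply(masks, inherits, logical(1), "qc_mask")))
  n <- masks[[1]]$original_n
  if (!all(vapply(masks, `[[`, integer(1), "original_n") == n))
    abort_sm("masks cover different original pixel counts", "mask")
  keep <- Reduce(`&`, lapply(masks, `[[`, "keep"))
  reason <- rep(NA_character_, n)
  for (m in rev(masks)) reason[!m$keep] <- m$reason[!m$keep]  # first mask wins
  qc_mask(keep, ifelse(keep, NA_character_, reason))
}

qc_window_idx <- function(map, window, what) {
  idx <- axis_in_window(map$axis, window[1], window[2])
  if (!length(idx))
    abort_sm(sprintf("%s [%g, %g] cm^-1 does not overlap the axis (%g..%g)",
                     what, window[1], window[2],
                     map$axis[1], map$axis[length(map$axis)]), "window")
  idx
}

#' Detect empty positions (holes, off-sample pixels)
#'
#' Flags a pixel as `empty` when its mean absorbance inside
#' `params$empty_window` falls below `params$empty_threshold`: positions
#' with no sample show essentially no amide I absorption.
#'
#' @param map A [spectral_map].
#' @param params [preprocess_params].
#' @return A [qc_mask] over the map's pixels (reason `"empty"`).
#' @export
detect_empty <- function(map, params = preprocess_params()) {
  stopifnot(inherits(map, "spectral_map"))
  idx <- qc_window_idx(map, params$empty_window, "empty_window")
  m <- rowMeans(map$absorbance[, idx, drop = FALSE])
  keep <- m >= params$empty_threshold
  qc_mask(keep, ifelse(keep, NA_character_, "empty"))
}

#' Detect light-scattering outlier spectra
#'
#' Flags a pixel as `scatter` when either (a) the absolute least-squares
#' slope of its absorbance over the spectroscopically silent window exceeds
#' `scatter_slope_threshold` — the broad sloping baseline characteristic of
#' Mie-type scattering — or (b) the fraction of negative absorbance values
#' over the full spectrum exceeds `scatter_negative_fraction_threshold`.
#'
#' @inheritParams detect_empty
#' @return A [qc_mask] over the map's pixels (reason `"scatter"`).
#' @export
detect_scatter <- function(map, params = preprocess_params()) {
  stopifnot(inherits(map, "spectral_map"))
  idx <- qc_window_idx(map, params$scatter_silent_window, "scatter_silent_window")
  w <- map$axis[idx]
  wc <- w - mean(w)
  denom <- sum(wc^2)
  A <- map$absorbance[, idx, drop = FALSE]
  slope <- if (denom > 0) as.numeric(A %*% wc) / denom else
    rep(0, nrow(map$absorbance))
  neg_frac <- rowMeans(map$absorbance < 0)
  bad <- abs(slope) > params$scatter_slope_threshold |
    neg_frac > params$scatter_negative_fraction_threshold
  qc_mask(!bad, ifelse(bad, "scatter", NA_character_))
}

#' Apply a QC mask to a spectral map
#'
#' Drops excluded pixel rows, preserving original order. The mask is stored
#' on the result (`attr(., "qc_mask")`) so excluded positions can later be
#' repopulated for spatial mapping.
#'
#' @param map A [spectral_map].
#' @param mask A [qc_mask] with `original_n == nrow(map$absorbance)`.
#' @return A [spectral_map] of the retained pixels (grid metadata kept for
#'   later spatial reconstruction, even though retained count no longer
#'   equals `nx * ny`).
#' @export
apply_mask <- function(map, mask) {
  stopifnot(inherits(map, "spectral_map"), inherits(mask, "qc_mask"))
  if (mask$original_n != nrow(map$absorbance))
    abort_sm(sprintf("mask covers %d pixels but map has %d",
                     mask$original_n, nrow(map$absorbance)), "mask")
  out <- map
  out$absorbance <- map$absorbance[mask$keep, , drop = FALSE]
  out$sample_ids <- map$sample_ids[mask$keep]
  out$grid <- NULL
  attr(out, "qc_mask") <- mask
  attr(out, "source_grid") <- map$grid
  sm_log(out, sprintf("QC mask applied: %d of %d pixels retained",
                      sum(mask$keep), mask$original_n))
}

#' Excise the atmospheric CO2 region
#'
#' Removes every axis point inside the closed `co2_window` (default
#' 2300-2400 cm^-1, the atmospheric CO2 asymmetric stretch) so that
#' atmosphere-driven variation cannot create batch effects in clustering.
#' A window disjoint from the axis is a no-op; the operation is idempotent.
#'
#' @inheritParams detect_empty
#' @return A [spectral_map] with the CO2 columns removed.
#' @export
exclude_co2 <- function(map, params = preprocess_params()) {
  stopifnot(inherits(map, "spectral_map"))
  drop <- axis_in_window(map$axis, params$co2_window[1], params$co2_window[2])
  if (!length(drop)) return(map)
  out <- map
  out$axis <- map$axis[-drop]
  out$absorbance <- map$absorbance[, -drop, drop = FALSE]
  sm_log(out, sprintf("CO2 region [%g, %g] cm^-1 excised: %d columns removed",
                      params$co2_window[1], params$co2_window[2], length(drop)))
}

#' Vector-normalize retained spectra
#'
#' Scales each pixel spectrum to unit Euclidean norm, removing
#' thickness/concentration effects. Apply only after QC: a zero-norm row
#' (which should have been excluded as empty) is an error.
#'
#' @param map A [spectral_map] containing retained pixels only.
#' @return A [spectral_map] whose rows all have Euclidean norm 1.
#' @export
vector_normalize <- function(map) {
  stopifnot(inherits(map, "spectral_map"))
  nrm <- sqrt(rowSums(map$absorbance^2))
  if (any(nrm == 0))
    abort_sm(sprintf("degenerate zero-norm spectrum at pixel row(s): %s",
                     paste(which(nrm == 0), collapse = ", ")),
             "degenerate_spectrum")
  out <- map
  out$absorbance <- map$absorbance / nrm
  sm_log(out, "vector normalization (unit Euclidean norm per spectrum)")
}

#' Savitzky-Golay second derivative
#'
#' Returns the second derivative of each spectrum with respect to
#' wavenumber (units absorbance * cm^2), estimated by Savitzky-Golay
#' polynomial filtering. The second derivative annihilates constant and
#' linear baseline components — the standard control for baseline variation
#' at collection time — and sharpens overlapping bands. Edge points are
#' filled with the local polynomial fit evaluated at the edges, so the axis
#' is unchanged. Requires a uniformly spaced axis.
#'
#' @inheritParams detect_empty
#' @return A [spectral_map] of second-derivative spectra on the same axis.
#' @export
second_derivative <- function(map, params = preprocess_params()) {
  stopifnot(inherits(map, "spectral_map"))
  h <- diff(map$axis)
  spacing <- stats::median(h)
  # A previously excised region (e.g. CO2) leaves a gap in an otherwise
  # uniform axis: filter each contiguous uniformly spaced segment
  # independently rather than across the gap.
  gap <- abs(h - spacing) / spacing > 1e-6
  seg_id <- cumsum(c(0L, as.integer(gap)))      # segment id per axis point
  seg_lens <- as.integer(table(seg_id))
  if (any(seg_lens < params$sg_window_pts))
    abort_sm(paste("axis must be uniformly spaced (within each contiguous",
                   "segment) and every segment at least sg_window_pts long"),
             "spacing")
  out <- map
  bounds <- c(0L, cumsum(seg_lens))
  D <- map$absorbance
  for (s in seq_along(seg_lens)) {
    cols <- (bounds[s] + 1L):bounds[s + 1L]
    D[, cols] <- t(apply(map$absorbance[, cols, drop = FALSE], 1, function(x)
      signal::sgolayfilt(x, p = params$sg_polyorder, n = params$sg_window_pts,
                         m = 2, ts = spacing)))
  }
  out$absorbance <- D
  sm_log(out, sprintf(
    "Savitzky-Golay 2nd derivative (window %d pts, order %d, spacing %g cm^-1, %d segment(s))",
    params$sg_window_pts, params$sg_polyorder, spacing, length(seg_lens)))
}

#' Write / read a QC mask as delimited text
#'
#' Columns: `pixel_index` (0-based, original order), `keep` (0/1), `reason`.
#'
#' @param mask A [qc_mask].
#' @param path File path.
#' @return `write_qc_mask`: invisibly, `path`. `read_qc_mask`: a [qc_mask].
#' @export
write_qc_mask <- function(mask, path) {
  stopifnot(inherits(mask, "qc_mask"))
  df <- data.frame(pixel_index = seq_len(mask$original_n) - 1L,
                   keep = as.integer(mask$keep),
                   reason = ifelse(is.na(mask$reason), "", mask$reason))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qc_mask
#' @export
read_qc_mask <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer", "character"))
  qc_mask(df$keep == 1L, ifelse(df$keep == 1L, NA_character_, df$reason))
}
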