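#' Repopulate excluded positions
#'
#' Expands a per-retained-pixel result vector back to the original pixel
#' order using the saved QC mask: retained values land in their original
#' positions, excluded positions hold `NA` (the missing marker). This is
#' the bookkeeping that lets QC-excluded holes reappear as gaps in spatial
#' maps rather than silently shifting the raster.
#'
#' @param values Vector with one entry per retained (`keep == TRUE`) pixel.
#' @param mask The [qc_mask] that produced the retained subset.
#' @return Vector of length `mask$original_n`; `NA` at excluded positions.
#' @export
repopulate <- function(values, mask) {
  stopifnot(inherits(mask, "qc_mask"))
  if (length(values) != sum(mask$keep))
    abort_sm(sprintf("got %d values for %d retained pixels",
                     length(values), sum(mask$keep)), "mask")
  out <- rep(values[NA_integer_][1], mask$original_n)   # NA of values' type
  out[mask$keep] <- values
  out
}

#' Reshape a full-length pixel vector to acquisition layout
#'
#' Fills the acquisition grid row-major from the top-left with x varying
#' fastest: pixel `i` (0-based) goes to grid row `floor(i / nx)`, column
#' `i %% nx` — the declared raster convention of [grid_spec].
#'
#' @param full_values Vector of length `nx * ny` (typically from
#'   [repopulate]).
#' @param grid A [grid_spec].
#' @param kind `"scalar"` or `"label"`.
#' @return An object of class `spatial_image`: `values` (`ny x nx`
#'   matrix, `NA` marks missing), `kind`, `grid`.
#' @export
to_grid <- function(full_values, grid, kind = c("scalar", "label")) {
  stopifnot(inherits(grid, "grid_spec"))
  kind <- match.arg(kind)
  if (length(full_values) != grid$nx * grid$ny)
    abort_sm(sprintf("vector length %d does not match grid nx*ny = %d",
                     length(full_values), grid$nx * grid$ny), "shape")
  structure(list(values = matrix(full_values, nrow = grid$ny,
                                 ncol = grid$nx, byrow = TRUE),
                 kind = kind, grid = grid),
            class = "spatial_image")
}

#' Flatten a spatial image back to pixel order
#'
#' Inverse of [to_grid] under the declared raster convention.
#'
#' @param image A `spatial_image`.
#' @return Vector of length `nx * ny` in original pixel order.
#' @export
flatten_grid <- function(image) {
  stopifnot(inherits(image, "spatial_image"))
  as.vector(t(image$values))
}

#' @export
print.spatial_image <- function(x, ...) {
  cat(sprintf("<spatial_image> %d x %d (%s), %d missing\n",
              x$grid$ny, x$grid$nx, x$kind, sum(is.na(x$values))))
  invisible(x)
}

#' Map integrated band areas across the tissue
#'
#' Convenience chain `integrate_band` -> `repopulate` -> `to_grid`:
#' renders the chemical content estimated by a band area as a scalar map
#' in acquisition layout, with QC-excluded positions missing. Optionally
#' writes a rendered PNG plus a machine-checkable sidecar text grid.
#'
#' @param map A [spectral_map] of retained pixels.
#' @param mask The [qc_mask] used to retain them.
#' @param grid A [grid_spec] for the original acquisition.
#' @param window A [band_window].
#' @param file Optional output path stem; writes `<file>.png` and
#'   `<file>.txt`.
#' @return A `spatial_image` of kind `"scalar"`.
#' @export
map_band <- function(map, mask, grid, window, file = NULL) {
  quant <- integrate_band(map, window)
  img <- to_grid(repopulate(quant$values, mask), grid, kind = "scalar")
  if (!is.null(file)) write_spatial_image(img, file)
  img
}

#' Map cluster labels across the tissue
#'
#' Renders a cluster assignment as a categorical map in acquisition
#' layout (`repopulate` -> `to_grid`), excluded positions missing.
#'
#' @param labels A `cluster_assignment` (or integer vector) over retained
#'   pixels.
#' @param mask The [qc_mask] used to retain them.
#' @param grid A [grid_spec].
#' @param file Optional output path stem (PNG + sidecar text grid).
#' @return A `spatial_image` of kind `"label"`.
#' @export
map_clusters <- function(labels, mask, grid, file = NULL) {
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else
    as.integer(labels)
  img <- to_grid(repopulate(lab, mask), grid, kind = "label")
  if (!is.null(file)) write_spatial_image(img, file)
  img
}

#' Write a spatial image to disk
#'
#' Writes `<stem>.png` (rendered image) and `<stem>.txt` (tab-delimited
#' grid of exact values, missing as `NA`), so every map is both viewable
#' and machine-checkable bit-exactly. Scalar maps use a sequential
#' colormap; label maps use a qualitative palette with a legend file
#' `<stem>_legend.txt` keyed by cluster label. Missing positions are
#' rendered magenta — a reserved colour outside both palettes.
#'
#' @param image A `spatial_image`.
#' @param stem Output path stem (no extension).
#' @return Invisibly, the stem.
#' @export
write_spatial_image <- function(image, stem) {
  stopifnot(inherits(image, "spatial_image"))
  utils::write.table(image$values, paste0(stem, ".txt"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  v <- image$values
  rgb_arr <- array(0, dim = c(nrow(v), ncol(v), 3))
  miss <- is.na(v)
  if (all(miss)) {
    cols <- matrix(0, 3, length(v))
  } else if (image$kind == "scalar") {
    rng <- range(v, na.rm = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    pal <- grDevices::hcl.colors(256, "viridis")
    idx <- pmin(255L, pmax(0L, as.integer(round((v - rng[1]) / span * 255))))
    idx[miss] <- 0L                             # placeholder, overdrawn below
    cols <- grDevices::col2rgb(pal[idx + 1L]) / 255
  } else {
    labs <- sort(unique(v[!miss]))
    pal <- grDevices::hcl.colors(max(length(labs), 2L), "Dark 3")
    utils::write.table(
      data.frame(label = labs, color = pal[seq_along(labs)]),
      paste0(stem, "_legend.txt"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    idx <- match(v, labs)
    idx[miss] <- 1L                             # placeholder, overdrawn below
    cols <- grDevices::col2rgb(pal[idx]) / 255
  }
  for (ch in 1:3) {
    plane <- matrix(cols[ch, ], nrow = nrow(v), ncol = ncol(v))
    plane[miss] <- c(1, 0, 1)[ch]               # reserved magenta
    rgb_arr[, , ch] <- plane
  }
  png::writePNG(rgb_arr, paste0(stem, ".png"))
  invisible(stem)
}
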