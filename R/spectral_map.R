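#' Acquisition grid metadata
#'
#' Describes the raster layout of a mapping acquisition: `nx` spectra along
#' x (columns), `ny` along y (rows). The raster order is row-major with the
#' origin at the top-left and x varying fastest; pixel `i` (0-based) maps to
#' grid row `floor(i / nx)` and column `i %% nx`.
#'
#' @param nx,ny Number of spectra acquired along the x and y axes (>= 1).
#' @param raster_order Raster convention; only `"row_major_top_left"` is
#'   currently defined.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, raster_order = "row_major_top_left") {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 1L || ny < 1L)
    abort_sm("grid dimensions nx and ny must be integers >= 1", "parameter")
  raster_order <- match.arg(raster_order, "row_major_top_left")
  structure(list(nx = nx, ny = ny, raster_order = raster_order),
            class = "grid_spec")
}

#' Spectral map container
#'
#' The central object of the package: a dense absorbance matrix with one row
#' per pixel (spectrum) and one column per wavenumber, a strictly ascending
#' wavenumber axis in cm^-1, per-pixel sample identifiers and optional
#' acquisition-grid metadata. All operations in the package take and return
#' this container.
#'
#' @param absorbance Numeric matrix, `n_pixels x n_wavenumbers`.
#' @param axis Numeric vector of wavenumbers (cm^-1), strictly increasing,
#'   finite and positive, length equal to `ncol(absorbance)`. A strictly
#'   decreasing axis (the common instrument output order) is reversed on
#'   construction, together with the matrix columns.
#' @param sample_ids Character vector, one sample identifier per pixel row.
#'   A single value is recycled.
#' @param grid Optional [grid_spec]; if present, `nrow(absorbance)` must
#'   equal `nx * ny`.
#' @return An object of class `spectral_map` with elements `absorbance`,
#'   `axis`, `sample_ids`, `grid` and a character `log` of applied steps.
#' @export
spectral_map <- function(absorbance, axis, sample_ids = "sample1",
                         grid = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  axis <- as.numeric(axis)
  log <- character()
  if (length(axis) != ncol(absorbance))
    abort_sm(sprintf(
      "axis length (%d) must equal number of absorbance columns (%d)",
      length(axis), ncol(absorbance)), "shape")
  if (anyNA(axis) || any(!is.finite(axis)) || any(axis <= 0))
    abort_sm("wavenumber axis must be finite and > 0", "axis")
  if (length(axis) > 1) {
    d <- diff(axis)
    if (all(d < 0)) {            # descending instrument order: canonicalize
      axis <- rev(axis)
      absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
      log <- c(log, "axis reversed from descending to canonical ascending order")
    } else if (any(d <= 0)) {
      abort_sm("wavenumber axis must be strictly monotonic", "axis")
    }
  }
  if (nrow(absorbance) > 0 && ncol(absorbance) > 0) {
    all_na <- rowSums(!is.na(absorbance)) == 0L
    if (any(all_na))
      abort_sm(sprintf("pixel row(s) entirely missing-valued: %s",
                       paste(which(all_na), collapse = ", ")), "data")
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) == 1L) sample_ids <- rep(sample_ids, nrow(absorbance))
  if (length(sample_ids) != nrow(absorbance))
    abort_sm("sample_ids must have one entry per pixel row", "shape")
  if (!is.null(grid)) {
    if (!inherits(grid, "grid_spec")) abort_sm("grid must be a grid_spec", "parameter")
    if (grid$nx * grid$ny != nrow(absorbance))
      abort_sm(sprintf("grid nx*ny = %d does not match pixel count %d",
                       grid$nx * grid$ny, nrow(absorbance)), "shape")
  }
  dimnames(absorbance) <- NULL
  structure(list(absorbance = absorbance, axis = axis,
                 sample_ids = sample_ids, grid = grid, log = log),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map> %d pixels x %d wavenumbers\n",
              nrow(x$absorbance), ncol(x$absorbance)))
  if (length(x$axis))
    cat(sprintf("  axis: %.6g .. %.6g cm^-1\n", x$axis[1], x$axis[length(x$axis)]))
  cat(sprintf("  samples: %s\n", paste(unique(x$sample_ids), collapse = ", ")))
  if (!is.null(x$grid))
    cat(sprintf("  grid: %d x %d (%s)\n", x$grid$nx, x$grid$ny, x$grid$raster_order))
  invisible(x)
}

#' @export
dim.spectral_map <- function(x) dim(x$absorbance)

# Append a provenance line; every transforming operation calls this.
sm_log <- function(map, entry) {
  map$log <- c(map$log, entry)
  map
}

# Indices of axis points inside the closed interval [lo, hi].
axis_in_window <- function(axis, lo, hi) which(axis >= lo & axis <= hi)
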