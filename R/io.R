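#' Read a spectral matrix from delimited text
#'
#' Reads a plain-text spectral table into a [spectral_map]. The canonical
#' layout has wavenumbers in the first column and one spectrum per
#' subsequent column; the transposed layout (one spectrum per row,
#' wavenumbers in the header row) is selected with
#' `orientation = "pixels_in_rows"`. The delimiter (comma or tab) is
#' auto-detected unless given. Files with a descending wavenumber axis are
#' reversed on read to the package's canonical ascending order; the
#' reversal is recorded in the map's provenance log.
#'
#' @param path Path to a delimited text file (UTF-8, `.` decimal separator).
#' @param sep Field separator; `NULL` (default) auto-detects `,` vs tab.
#' @param orientation `"pixels_in_cols"` (default; wavenumbers are the first
#'   column) or `"pixels_in_rows"` (wavenumbers are the header row).
#' @param sample_id Sample identifier attached to every pixel of this file.
#' @param grid Optional [grid_spec] for the acquisition layout.
#' @return A [spectral_map].
#' @export
read_spectral_table <- function(path, sep = NULL,
                                orientation = c("pixels_in_cols", "pixels_in_rows"),
                                sample_id = NULL, grid = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    abort_sm(sprintf("file not found: %s", path), "io")
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  # first row is a header in both orientations
  header <- as.character(raw[1, ])
  body <- raw[-1, , drop = FALSE]
  parse_num <- function(x, what) {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v) & !(x %in% c("NA", "")))
    if (length(bad))
      abort_sm(sprintf("non-numeric %s value %s", what,
                       dQuote(x[bad[1]], q = FALSE)), "format")
    v
  }
  if (orientation == "pixels_in_cols") {
    axis <- parse_num(body[[1]], "wavenumber")
    vals <- vapply(seq_len(ncol(body))[-1],
                   function(j) parse_num(body[[j]], "absorbance"),
                   numeric(nrow(body)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(body))
    absorbance <- t(vals)       # pixels in rows internally
  } else {
    axis <- parse_num(header[-1], "wavenumber")
    absorbance <- matrix(0, nrow = nrow(body), ncol = length(axis))
    for (j in seq_along(axis) + 1L)
      absorbance[, j - 1L] <- parse_num(body[[j]], "absorbance")
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  map <- spectral_map(absorbance, axis, sample_ids = sample_id, grid = grid)
  sm_log(map, sprintf("read %d spectra x %d wavenumbers from %s",
                      nrow(map$absorbance), length(map$axis), path))
}

#' Write a spectral map to delimited text
#'
#' Writes the canonical layout read back by [read_spectral_table]:
#' wavenumbers in the first column, one spectrum per subsequent column,
#' header naming each pixel. Values are written with 15 significant digits
#' so a read/write round trip reproduces absorbances to better than 1e-12
#' relative error.
#'
#' @param map A [spectral_map].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_spectral_table <- function(map, path, sep = ",") {
  stopifnot(inherits(map, "spectral_map"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort_sm(
                    sprintf("cannot open %s for writing", path), "io"))
  on.exit(close(con))
  n_px <- nrow(map$absorbance)
  header <- c("wavenumber", if (n_px) paste0("px", seq_len(n_px) - 1L))
  writeLines(paste(header, collapse = sep), con)
  if (length(map$axis) && n_px) {
    num <- function(x) sprintf("%.15g", x)
    lines <- vapply(seq_along(map$axis), function(j) {
      paste(c(num(map$axis[j]), if (n_px) num(map$absorbance[, j])),
            collapse = sep)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a sample annotation table
#'
#' Delimited text with a mandatory `sample_name` column plus arbitrary
#' clinical or technical variables, one record per sample.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `NULL` auto-detects `,` vs tab.
#' @return A data.frame with a `sample_name` character column.
#' @export
read_annotations <- function(path, sep = NULL) {
  if (!file.exists(path)) abort_sm(sprintf("file not found: %s", path), "io")
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  ann <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (!"sample_name" %in% names(ann))
    abort_sm("annotation table must contain a sample_name column", "annotation")
  ann$sample_name <- as.character(ann$sample_name)
  ann
}

#' Concatenate samples on a common wavenumber axis
#'
#' Row-concatenates multiple per-sample maps for joint analysis. Axes must
#' be identical to within `tol` cm^-1 (absolute); there is no resampling —
#' silent interpolation would alter band areas, so differing axes are an
#' error. Per-pixel sample identifiers are preserved, and every sample must
#' appear in the annotation table if one is supplied.
#'
#' @param maps List of [spectral_map] objects (>= 1).
#' @param annotations Optional annotation data.frame with a `sample_name`
#'   column covering every sample id present.
#' @param tol Absolute axis agreement tolerance in cm^-1 (default `1e-6`).
#' @return A single [spectral_map]; rows in input order, grid dropped.
#' @export
concat_samples <- function(maps, annotations = NULL, tol = 1e-6) {
  if (!length(maps)) abort_sm("need at least one map", "parameter")
  stopifnot(all(vapply(maps, inherits, logical(1), "spectral_map")))
  axis0 <- maps[[1]]$axis
  for (m in maps[-1]) {
    if (length(m$axis) != length(axis0))
      abort_sm(sprintf("incompatible axes: lengths %d vs %d",
                       length(axis0), length(m$axis)), "incompatible_axes")
    d <- abs(m$axis - axis0)
    if (any(d > tol))
      abort_sm(sprintf(
        "incompatible axes: first differing wavenumber %.6g vs %.6g cm^-1",
        axis0[which(d > tol)[1]], m$axis[which(d > tol)[1]]),
        "incompatible_axes")
  }
  ids <- unlist(lapply(maps, `[[`, "sample_ids"))
  if (!is.null(annotations)) {
    missing <- setdiff(unique(ids), annotations$sample_name)
    if (length(missing))
      abort_sm(sprintf("sample(s) absent from annotations: %s",
                       paste(missing, collapse = ", ")), "annotation")
  }
  out <- spectral_map(do.call(rbind, lapply(maps, `[[`, "absorbance")),
                      axis0, sample_ids = ids)
  sm_log(out, sprintf("concatenated %d sample map(s), %d pixels total",
                      length(maps), length(ids)))
}

#' Broadcast sample-level annotations to pixels
#'
#' Joins a per-sample annotation table onto a map's pixels by
#' `sample_name`, yielding one annotation record per pixel row.
#'
#' @param map A [spectral_map].
#' @param annotations Data.frame with a `sample_name` column.
#' @return Data.frame with one row per pixel: `pixel_index` (0-based),
#'   `sample_name`, plus every annotation variable.
#' @export
pixel_annotations <- function(map, annotations) {
  idx <- match(map$sample_ids, annotations$sample_name)
  if (anyNA(idx))
    abort_sm(sprintf("sample(s) absent from annotations: %s",
                     paste(unique(map$sample_ids[is.na(idx)]), collapse = ", ")),
             "annotation")
  cbind(data.frame(pixel_index = seq_len(nrow(map$absorbance)) - 1L),
        annotations[idx, , drop = FALSE], row.names = NULL)
}
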