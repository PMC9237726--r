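#' Default wavenumber axis for synthetic scenes
#'
#' 950-3100 cm^-1 at 2 cm^-1 spacing: covers the fingerprint region
#' (nucleic acid phosphate, amide I/II) and the CH-stretch lipid region
#' while keeping matrices small.
#'
#' @param lo,hi,by Axis bounds and spacing, cm^-1.
#' @return Numeric wavenumber vector.
#' @export
default_axis <- function(lo = 950, hi = 3100, by = 2) seq(lo, hi, by = by)

# Gaussian absorption band evaluated on an axis.
gaussian_band <- function(axis, center, amplitude, sigma)
  amplitude * exp(-((axis - center)^2) / (2 * sigma^2))

#' Build the default ground-truthed synthetic tissue scene
#'
#' Generates a region-structured scene emulating an FPA tissue map: three
#' spatially contiguous region classes (vertical bands across the grid)
#' with distinct macromolecular signatures, ~2% empty holes, ~2%
#' scattering pixels, mild per-pixel affine baselines and channel noise.
#' All tissue classes carry amide I/II protein bands (tissue is never
#' protein-free); the classes differ in their dominant chemistry:
#'
#' * `protein` — strong amide I (1654) and amide II (1545);
#' * `lipid` — CH2 stretches (2920, 2850) plus moderate amide bands;
#' * `nucleic` — phosphate bands (1080, 1240) plus moderate amide bands.
#'
#' Everything is drawn from a generator seeded with `seed`, so the same
#' call always returns an identical scene.
#'
#' @param nx,ny Grid size (>= 4 each). Default 32 x 32.
#' @param seed Integer seed. Default 0.
#' @param hole_fraction,scatter_fraction Fractions of pixels seeded as
#'   holes / scattering artefacts. Defaults 0.02 each.
#' @param noise_sd Per-channel Gaussian noise standard deviation
#'   (absorbance). Default 0.005.
#' @param scatter_slope Baseline upslope added to scattering pixels,
#'   absorbance per cm^-1, anchored at the axis minimum so the distorted
#'   spectrum stays positive. Default 2.5e-3.
#' @return An object of class `synthetic_scene`: `grid`, integer
#'   `region_map` (1-based class per pixel in raster order),
#'   `class_signatures` (per class, data.frame of Gaussian band
#'   parameters), `holes` and `scatter_pixels` (pixel indices, 1-based),
#'   per-pixel `baseline` coefficients, `noise_sd`, `scatter_slope`,
#'   `seed`.
#' @export
make_default_scene <- function(nx = 32L, ny = 32L, seed = 0L,
                               hole_fraction = 0.02,
                               scatter_fraction = 0.02,
                               noise_sd = 0.005,
                               scatter_slope = 2.5e-3) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 4L || ny < 4L)
    abort_sm("scene grid must be at least 4 x 4", "parameter")
  grid <- grid_spec(nx, ny)
  n <- nx * ny
  # three contiguous vertical region bands
  col_of <- (seq_len(n) - 1L) %% nx
  breaks <- round(c(nx / 3, 2 * nx / 3))
  region_map <- ifelse(col_of < breaks[1], 1L,
                       ifelse(col_of < breaks[2], 2L, 3L))
  sig <- function(center, amplitude, sigma)
    data.frame(center = center, amplitude = amplitude, sigma = sigma)
  class_signatures <- list(
    protein = sig(c(1654, 1545),             c(1.0, 0.6),        c(15, 12)),
    lipid   = sig(c(2920, 2850, 1654, 1545), c(0.9, 0.6, 0.45, 0.25),
                  c(12, 10, 15, 12)),
    nucleic = sig(c(1080, 1240, 1650, 1545), c(0.8, 0.4, 0.5, 0.3),
                  c(15, 12, 15, 12)))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  n_holes <- max(1L, round(hole_fraction * n))
  n_scatter <- max(1L, round(scatter_fraction * n))
  special <- sample.int(n, n_holes + n_scatter)
  holes <- sort(special[seq_len(n_holes)])
  scatter_pixels <- sort(special[n_holes + seq_len(n_scatter)])
  # mild affine drifts that keep the baseline positive across the axis span
  # (tissue absorbance baselines drift but do not go negative)
  baseline <- data.frame(intercept = stats::runif(n, 0.01, 0.03),
                         slope = stats::runif(n, -4e-6, 4e-6))
  structure(list(grid = grid, region_map = region_map,
                 class_signatures = class_signatures,
                 holes = holes, scatter_pixels = scatter_pixels,
                 baseline = baseline, noise_sd = noise_sd,
                 scatter_slope = scatter_slope,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d grid, %d classes, %d holes, %d scatter pixels, seed %d\n",
              x$grid$nx, x$grid$ny, length(x$class_signatures),
              length(x$holes), length(x$scatter_pixels), x$seed))
  invisible(x)
}

#' Render a synthetic scene to a spectral map
#'
#' Per pixel: the sum of its region class's Gaussian bands, plus the
#' pixel's affine baseline (anchored at the axis minimum), plus — for
#' seeded scattering pixels — a steep positive baseline upslope, plus
#' independent Gaussian channel noise. Hole pixels carry noise only
#' (near-zero spectra). Rendering is seeded by the scene, so identical
#' scenes render to bitwise-identical maps.
#'
#' @param scene A [synthetic_scene].
#' @param axis Wavenumber axis; must cover every band center. Default
#'   [default_axis()].
#' @param sample_id Sample identifier for the rendered map.
#' @return A [spectral_map] with the scene's grid attached.
#' @export
render_scene <- function(scene, axis = default_axis(),
                         sample_id = "synthetic") {
  stopifnot(inherits(scene, "synthetic_scene"))
  axis <- as.numeric(axis)
  centers <- unlist(lapply(scene$class_signatures, `[[`, "center"))
  if (any(centers < min(axis) | centers > max(axis)))
    abort_sm(sprintf("band center(s) outside the axis: %s",
                     paste(centers[centers < min(axis) | centers > max(axis)],
                           collapse = ", ")), "configuration")
  n <- scene$grid$nx * scene$grid$ny
  k <- length(axis)
  # per-class clean signatures
  class_spectra <- vapply(scene$class_signatures, function(s)
    Reduce(`+`, Map(gaussian_band, list(axis), s$center, s$amplitude, s$sigma)),
    numeric(k))
  A <- t(class_spectra[, scene$region_map, drop = FALSE])
  w0 <- axis - axis[1]
  A <- A + outer(scene$baseline$intercept, rep(1, k)) +
    outer(scene$baseline$slope, w0)
  A[scene$holes, ] <- 0                               # no sample, no baseline
  A[scene$scatter_pixels, ] <- A[scene$scatter_pixels, , drop = FALSE] +
    outer(rep(scene$scatter_slope, length(scene$scatter_pixels)), w0)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(scene$seed + 1L)                           # noise stream
  if (scene$noise_sd > 0)
    A <- A + matrix(stats::rnorm(n * k, sd = scene$noise_sd), n, k)
  map <- spectral_map(A, axis, sample_ids = sample_id, grid = scene$grid)
  sm_log(map, sprintf("rendered synthetic scene (seed %d) on %d-point axis",
                      scene$seed, k))
}

#' Generate a ready-to-analyze multi-sample synthetic set
#'
#' Renders several case and control scenes, echoing a typical
#' disease-vs-control imaging study design: case scenes carry an amide I
#' position shifted toward beta-sheet (1650 -> shifted center in the
#' protein class), the classic signature of misfolded protein deposits.
#'
#' @param n_case,n_control Number of case / control samples. Default 3 each.
#' @param nx,ny Per-sample grid size. Default 32 x 32.
#' @param seed Base seed; sample `i` uses `seed + i`.
#' @param case_shift Amide I center shift (cm^-1) applied to case samples.
#'   Default `-12` (1654 -> 1642, toward the beta-sheet region).
#' @return List with `maps` (list of [spectral_map]), `annotations`
#'   (data.frame: `sample_name`, `condition`), `scenes`.
#' @export
make_sample_set <- function(n_case = 3L, n_control = 3L, nx = 32L, ny = 32L,
                            seed = 0L, case_shift = -12) {
  n_total <- n_case + n_control
  condition <- rep(c("case", "control"), c(n_case, n_control))
  names <- sprintf("%s%d", condition, c(seq_len(n_case), seq_len(n_control)))
  scenes <- vector("list", n_total)
  maps <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sc <- make_default_scene(nx, ny, seed = as.integer(seed) + i)
    if (condition[i] == "case") {
      for (cls in names(sc$class_signatures)) {
        ctr <- sc$class_signatures[[cls]]$center
        amide1 <- which(ctr >= 1648 & ctr <= 1660)
        sc$class_signatures[[cls]]$center[amide1] <- ctr[amide1] + case_shift
      }
    }
    scenes[[i]] <- sc
    maps[[i]] <- render_scene(sc, sample_id = names[i])
  }
  list(maps = maps,
       annotations = data.frame(sample_name = names, condition = condition),
       scenes = scenes)
}
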