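test_that("detect_empty matches a direct mean-and-compare loop and recovers holes", {
  fx <- default_scene_fixture()
  mask <- detect_empty(fx$map, preprocess_params())
  # independent oracle: explicit per-pixel loop
  idx <- which(fx$map$axis >= 1600 & fx$map$axis <= 1700)
  oracle <- vapply(seq_len(nrow(fx$map$absorbance)), function(i)
    mean(fx$map$absorbance[i, idx]) >= 0.1, logical(1))
  expect_identical(mask$keep, oracle)
  expect_identical(which(!mask$keep), as.integer(fx$scene$holes))
  expect_true(all(mask$reason[!mask$keep] == "empty"))
})

test_that("detect_empty boundary cases behave as specified", {
  axis <- seq(1600, 1700, by = 4)
  m <- spectral_map(matrix(runif(5 * length(axis), 0, 1), 5), axis)
  p0 <- preprocess_params(empty_threshold = 0)
  expect_true(all(detect_empty(m, p0)$keep))   # absorbance >= 0 by construction
  zero <- spectral_map(matrix(0, 4, length(axis)), axis)
  mz <- detect_empty(zero, preprocess_params(empty_threshold = 0.1))
  expect_true(all(!mz$keep))
  expect_true(all(mz$reason == "empty"))
  expect_error(detect_empty(m, preprocess_params(empty_window = c(3000, 3100))),
               class = "spectromap_error_window")
})

test_that("detect_scatter flags sloped baselines via the least-squares criterion", {
  axis <- seq(1000, 3000, by = 2)
  flat <- 0.2 + numeric(length(axis))
  sloped <- flat + 2e-3 * (axis - 1000)        # slope 2e-3 absorbance/cm^-1
  m <- spectral_map(rbind(flat, sloped), axis)
  p <- preprocess_params(scatter_slope_threshold = 1e-3)
  mask <- detect_scatter(m, p)
  # oracle: closed-form least-squares slope over the silent window
  idx <- which(axis >= 1800 & axis <= 2600)
  sl <- stats::lsfit(axis[idx], sloped[idx])$coefficients[2]
  expect_gt(abs(sl), 1e-3)
  expect_identical(mask$keep, c(TRUE, FALSE))
  expect_identical(mask$reason[2], "scatter")
})

test_that("detect_scatter flags mostly-negative spectra and keeps flat ones", {
  axis <- seq(1000, 3000, by = 2)
  m <- spectral_map(matrix(-0.1, 1, length(axis)), axis)
  p <- preprocess_params(scatter_negative_fraction_threshold = 0.5)
  expect_false(detect_scatter(m, p)$keep)
  flat <- spectral_map(matrix(0.3, 1, length(axis)), axis)
  expect_true(detect_scatter(flat, preprocess_params())$keep)
})

test_that("detect_scatter recovers exactly the seeded scatter pixels", {
  fx <- default_scene_fixture()
  mask <- detect_scatter(fx$map, preprocess_params())
  expect_identical(which(!mask$keep), as.integer(fx$scene$scatter_pixels))
})

test_that("mask combination ANDs keeps, is order-independent, first reason wins", {
  k1 <- qc_mask(c(TRUE, FALSE, TRUE, FALSE),
                c(NA, "empty", NA, "empty"))
  k2 <- qc_mask(c(TRUE, FALSE, FALSE, TRUE),
                c(NA, "scatter", "scatter", NA))
  c12 <- combine_masks(k1, k2)
  c21 <- combine_masks(k2, k1)
  expect_identical(c12$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(c12$keep, c21$keep)          # order-independent keeps
  expect_identical(c12$reason[2], "empty")      # first mask wins on conflict
  expect_identical(c21$reason[2], "scatter")
  expect_identical(c12$reason[3], "scatter")    # only k2 excluded pixel 3
})

test_that("apply_mask subsets rows in original order and validates length", {
  m <- tiny_map(5, 6)
  mask <- qc_mask(c(TRUE, FALSE, TRUE, FALSE, TRUE))
  sub <- apply_mask(m, mask)
  expect_identical(sub$absorbance, m$absorbance[c(1, 3, 5), ])
  expect_identical(apply_mask(m, qc_mask(rep(TRUE, 5)))$absorbance,
                   m$absorbance)
  none <- apply_mask(m, qc_mask(rep(FALSE, 5)))
  expect_identical(nrow(none$absorbance), 0L)
  expect_error(apply_mask(m, qc_mask(rep(TRUE, 4))),
               class = "spectromap_error_mask")
})

test_that("QC mask round-trips through its delimited-text serialization", {
  mask <- qc_mask(c(TRUE, FALSE, TRUE, FALSE), c(NA, "empty", NA, "scatter"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_qc_mask(mask, path)
  back <- read_qc_mask(path)
  expect_identical(back$keep, mask$keep)
  expect_identical(back$reason, mask$reason)
})

test_that("CO2 excision removes the closed window, is idempotent, no-ops when disjoint", {
  axis <- seq(1000, 3000, by = 2)
  m <- spectral_map(matrix(runif(2 * length(axis)), 2), axis)
  out <- exclude_co2(m, preprocess_params(co2_window = c(2300, 2400)))
  expect_identical(ncol(m$absorbance) - ncol(out$absorbance), 51L)
  expect_false(any(out$axis >= 2300 & out$axis <= 2400))
  twice <- exclude_co2(out, preprocess_params(co2_window = c(2300, 2400)))
  expect_identical(twice$absorbance, out$absorbance)
  noop <- exclude_co2(m, preprocess_params(co2_window = c(9000, 9100)))
  expect_identical(noop$absorbance, m$absorbance)
})

test_that("vector normalization yields unit rows, idempotent and scale-invariant", {
  m34 <- spectral_map(matrix(c(3, 4), 1), c(1000, 1010))
  expect_equal(vector_normalize(m34)$absorbance, matrix(c(0.6, 0.8), 1))
  m <- tiny_map(10, 50, seed = 7)
  nm <- vector_normalize(m)
  expect_true(all(abs(sqrt(rowSums(nm$absorbance^2)) - 1) < 1e-10))
  expect_equal(vector_normalize(nm)$absorbance, nm$absorbance,
               tolerance = 1e-12)
  scaled <- m; scaled$absorbance <- 7.3 * m$absorbance
  expect_equal(vector_normalize(scaled)$absorbance, nm$absorbance,
               tolerance = 1e-12)
  zero <- spectral_map(matrix(0, 2, 3), c(1, 2, 3) + 1000)
  expect_error(vector_normalize(zero),
               class = "spectromap_error_degenerate_spectrum")
})

test_that("second derivative annihilates affine baselines and is exact on quadratics", {
  axis <- seq(1000, 1100, by = 1)
  a <- 2.5; b <- -0.03
  affine <- spectral_map(matrix(a + b * axis, 1), axis)
  d2 <- second_derivative(affine, preprocess_params())
  expect_lt(max(abs(d2$absorbance)), 1e-9)
  quad <- spectral_map(matrix(axis^2, 1), axis)
  d2q <- second_derivative(quad, preprocess_params())
  interior <- 5:(length(axis) - 4)
  expect_true(all(abs(d2q$absorbance[1, interior] - 2) < 1e-8))
  # constant offsets leave the derivative unchanged (baseline invariance)
  m <- tiny_map(3, 101, seed = 5, lo = 1000, by = 1)
  shifted <- m; shifted$absorbance <- m$absorbance + 0.7
  expect_equal(second_derivative(shifted)$absorbance,
               second_derivative(m)$absorbance, tolerance = 1e-9)
})

test_that("second derivative rejects non-uniform axes and short windows", {
  axis <- c(seq(1000, 1050, by = 1), seq(1052.5, 1100, by = 2.5))
  m <- spectral_map(matrix(runif(length(axis)), 1), axis)
  expect_error(second_derivative(m), class = "spectromap_error_spacing")
  expect_error(preprocess_params(sg_window_pts = 4),
               class = "spectromap_error_parameter")
  expect_error(preprocess_params(sg_polyorder = 1),
               class = "spectromap_error_parameter")
})

test_that("second derivative after CO2 excision filters each segment independently", {
  axis <- seq(2000, 2700, by = 2)
  set.seed(9)
  m <- spectral_map(matrix(runif(2 * length(axis)), 2), axis)
  cut <- exclude_co2(m, preprocess_params(co2_window = c(2300, 2400)))
  d2 <- second_derivative(cut, preprocess_params())
  # oracle: run the filter on each uniformly spaced piece separately
  left <- select_region(cut, 2000, 2298)
  right <- select_region(cut, 2402, 2700)
  expect_equal(d2$absorbance,
               cbind(second_derivative(left)$absorbance,
                     second_derivative(right)$absorbance),
               tolerance = 1e-12)
})

test_that("QC detection never changes the data; transforms never change pixel count", {
  fx <- default_scene_fixture()
  before <- fx$map$absorbance
  invisible(detect_empty(fx$map)); invisible(detect_scatter(fx$map))
  expect_identical(fx$map$absorbance, before)
  p <- preprocess_params()
  n <- nrow(fx$map$absorbance)
  expect_identical(nrow(exclude_co2(fx$map, p)$absorbance), n)
  expect_identical(nrow(vector_normalize(fx$map)$absorbance), n)
  expect_identical(nrow(second_derivative(fx$map, p)$absorbance), n)
})
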