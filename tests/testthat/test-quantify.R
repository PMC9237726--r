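test_that("band integration: rectangle, chord baseline, analytic Gaussian", {
  axis <- seq(1000, 1100, by = 1)
  m <- spectral_map(matrix(1, 1, length(axis)), axis)
  expect_equal(integrate_band(m, band_window(1025, 1075))$values, 50)
  expect_equal(
    integrate_band(m, band_window(1025, 1075, "linear_endpoints"))$values, 0)
  # Gaussian amplitude 1, sigma 10, 1 cm^-1 spacing, wide window
  axis2 <- seq(1500, 1800, by = 1)
  g <- band_map(axis2, 1650, 1, 10)
  area <- integrate_band(g, band_window(1500, 1800))$values
  expect_lt(abs(area - sqrt(2 * pi) * 10) / (sqrt(2 * pi) * 10), 0.005)
})

test_that("band integration is linear in the spectrum", {
  axis <- seq(1200, 1400, by = 2)
  set.seed(21)
  x <- runif(length(axis)); y <- runif(length(axis))
  w <- band_window(1250, 1350)
  area <- function(v) integrate_band(spectral_map(matrix(v, 1), axis), w)$values
  expect_equal(area(2.5 * x - 1.2 * y), 2.5 * area(x) - 1.2 * area(y),
               tolerance = 1e-12)
})

test_that("trapezoid error on a truncated Gaussian shrinks >= 3x when spacing halves", {
  sigma <- 10; center <- 1650
  analytic <- sqrt(2 * pi) * sigma * (stats::pnorm(2) - stats::pnorm(-2))
  err <- function(h) {
    axis <- seq(center - 2 * sigma, center + 2 * sigma, by = h)
    g <- band_map(axis, center, 1, sigma)
    abs(integrate_band(g, band_window(axis[1], axis[length(axis)]))$values -
          analytic)
  }
  expect_gte(err(1) / err(0.5), 3)
  expect_gte(err(2) / err(1), 3)
})

test_that("window errors require >= 2 points", {
  axis <- seq(1000, 1100, by = 10)
  m <- spectral_map(matrix(1, 1, length(axis)), axis)
  expect_error(integrate_band(m, band_window(1001, 1009)),
               class = "spectromap_error_window")
})

test_that("adjust_window centers on the located peak with stated tie-breaks", {
  axis <- seq(1600, 1700, by = 1)
  shifted <- band_map(axis, 1660, 1, 5)         # peak rendered at 1660
  w <- adjust_window(shifted, nominal_center = 1655, half_width = 15,
                     search_radius = 10)
  expect_equal((w$lo + w$hi) / 2, 1660)
  centered <- band_map(axis, 1655, 1, 5)
  w2 <- adjust_window(centered, 1655, 15, 10)
  expect_equal((w2$lo + w2$hi) / 2, 1655)
  flat <- spectral_map(matrix(1, 1, length(axis)), axis)
  w3 <- adjust_window(flat, 1655, 10, 8)        # all ties -> nominal center
  expect_equal((w3$lo + w3$hi) / 2, 1655)
  expect_error(adjust_window(flat, 500, 10, 5),
               class = "spectromap_error_window")
})

test_that("adjust_window clips to the axis range", {
  axis <- seq(1600, 1700, by = 1)
  edge <- band_map(axis, 1698, 1, 4)
  w <- adjust_window(edge, 1695, half_width = 20, search_radius = 5)
  expect_lte(w$hi, 1700)
  expect_equal(w$hi, 1700)
})

test_that("cluster mean spectra reduce correctly and recover class signatures", {
  m <- tiny_map(4, 6, seed = 2)
  one <- cluster_mean_spectra(m, rep(0L, 4))
  expect_equal(as.numeric(one[1, ]), colMeans(m$absorbance))
  two <- cluster_mean_spectra(
    spectral_map(m$absorbance[1:2, ], m$axis), c(0L, 1L))
  expect_equal(unname(two), unname(m$absorbance[1:2, ]))
  expect_error(cluster_mean_spectra(m, c(0L, 1L)),
               class = "spectromap_error_label")
  # scene: means per ground-truth region correlate with class signatures
  fx <- default_scene_fixture()
  mask <- combine_masks(detect_empty(fx$map), detect_scatter(fx$map))
  ret <- apply_mask(fx$map, mask)
  means <- cluster_mean_spectra(ret, fx$scene$region_map[mask$keep] - 1L)
  for (k in 1:3) {
    s <- fx$scene$class_signatures[[k]]
    clean <- rowSums(mapply(function(c, a, sg)
      a * exp(-((ret$axis - c)^2) / (2 * sg^2)), s$center, s$amplitude, s$sigma))
    expect_gte(stats::cor(means[k, ], clean), 0.99)
  }
})

test_that("secondary structure: pure helix band, 50/50 mixture, normalization", {
  axis <- seq(1580, 1720, by = 1)
  pure <- band_map(axis, 1654, 1, 3)
  fr <- estimate_secondary_structure(pure)
  expect_gte(fr$alpha_helix[1], 0.9)
  cls <- c("alpha_helix", "beta_sheet", "turns", "other")
  expect_equal(sum(fr[1, cls]), 1, tolerance = 1e-9)
  mix <- band_map(axis, c(1654, 1630), c(1, 1), c(3, 3))  # equal areas
  fm <- estimate_secondary_structure(mix)
  expect_equal(fm$alpha_helix[1], 0.5, tolerance = 0.05)
  expect_equal(fm$beta_sheet[1], 0.5, tolerance = 0.05)
  expect_equal(sum(fm[1, cls]), 1, tolerance = 1e-9)
})

test_that("secondary structure fractions are scale-invariant and flag zero pixels", {
  axis <- seq(1580, 1720, by = 1)
  mixed <- band_map(axis, c(1654, 1630, 1665), c(1, 0.7, 0.4), c(3, 3, 3))
  f1 <- estimate_secondary_structure(mixed)
  scaled <- mixed; scaled$absorbance <- 37 * mixed$absorbance
  f2 <- estimate_secondary_structure(scaled)
  cls <- c("alpha_helix", "beta_sheet", "turns", "other")
  expect_equal(as.numeric(f1[1, cls]), as.numeric(f2[1, cls]),
               tolerance = 1e-9)
  zero <- spectral_map(matrix(0, 1, length(axis)), axis)
  fz <- estimate_secondary_structure(zero)
  expect_true(fz$undefined[1])
  expect_true(all(is.na(fz[1, cls])))
  off_axis <- spectral_map(matrix(1, 1, 11), seq(2800, 2900, by = 10))
  expect_error(estimate_secondary_structure(off_axis),
               class = "spectromap_error_configuration")
})

test_that("structure coefficient tables are configurable and readable from YAML", {
  custom <- structure_coefficients(list(
    sheet = list(band_window(1620, 1640)),
    helix = list(band_window(1648, 1660))))
  expect_identical(custom$classes, c("sheet", "helix"))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("amide_window: [1600, 1700]",
               "helix:", "  - '1648:1660'",
               "sheet:", "  - '1620:1640'", "  - '1670:1695'"), path)
  cfg <- read_structure_coefficients(path)
  expect_setequal(cfg$classes, c("helix", "sheet"))
  expect_length(cfg$bands$sheet, 2)
})

test_that("group_values produces a tidy partition of pixels", {
  m <- tiny_map(4, 12, seed = 8, lo = 1600, by = 5)
  m$sample_ids <- c("a", "a", "b", "b")
  ann <- data.frame(sample_name = c("a", "b"), condition = c("case", "ctrl"))
  q <- integrate_band(m, band_window(1610, 1650))
  gv <- group_values(q, m, ann, "condition")
  expect_identical(nrow(gv), 4L)
  expect_identical(gv$group, c("case", "case", "ctrl", "ctrl"))
  counts <- table(group_values(q, m, ann, "sample_name")$group)
  expect_identical(as.integer(counts), c(2L, 2L))   # partition property
  empty <- integrate_band(
    spectral_map(matrix(numeric(0), 0, 12), m$axis), band_window(1610, 1650))
  ge <- group_values(empty, spectral_map(matrix(numeric(0), 0, 12), m$axis),
                     ann, "condition")
  expect_identical(nrow(ge), 0L)
  expect_error(group_values(q, m, ann, "nonexistent"),
               class = "spectromap_error_annotation")
})
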