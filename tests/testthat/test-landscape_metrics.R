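test_that("biovolume integrates analytic shapes", {
  slab <- as_grid(matrix(1.0, 10, 10))
  expect_equal(biovolume(slab), 100 * 1.0 * 0.04^2)   # 0.16 mm^3
  expect_equal(biovolume(as_grid(matrix(0, 5, 5))), 0)
  # discrete hemisphere, radius 0.5 mm at 40 um pixels
  px <- 0.04; r <- 0.5
  n <- 31
  cc <- (seq_len(n) - (n + 1) / 2) * px
  d2 <- outer(cc^2, cc^2, `+`)
  hemi <- ifelse(d2 <= r^2, sqrt(pmax(r^2 - d2, 0)), 0)
  expect_equal(biovolume(as_grid(hemi)), (2 / 3) * pi * r^3,
               tolerance = 0.05)
  # additive over disjoint regions
  g <- as_grid(matrix(runif(200), 10, 20))
  expect_equal(biovolume(g, c(1, 10, 1, 7)) + biovolume(g, c(1, 10, 8, 20)),
               biovolume(g))
})

test_that("coverage counts pixels above the detection threshold", {
  h <- matrix(0, 10, 10); h[, 1:5] <- 0.5
  g <- as_grid(h)
  expect_equal(coverage(g, h_min = 0.01), 0.5)
  expect_equal(coverage(as_grid(matrix(0, 4, 4))), 0)
  expect_equal(coverage(as_grid(matrix(0.3, 4, 4)), h_min = 0.01), 1)
  # planted landscape: known covered count
  set.seed(21)
  h2 <- matrix(0, 15, 15)
  idx <- sample(225, 60)
  h2[idx] <- runif(60, 0.05, 1)
  expect_equal(coverage(as_grid(h2), h_min = 0.01), 60 / 225)
  expect_error(coverage(g, region = c(5, 4, 1, 10)), "region")
})

test_that("height statistics cover the covered pixels and flag empty regions", {
  expect_equal(height_stats(as_grid(matrix(0.3, 6, 6)))[1:3],
               list(mean_thickness = 0.3, max_height = 0.3, p99_height = 0.3))
  hs0 <- height_stats(as_grid(matrix(0, 6, 6)))
  expect_equal(unlist(hs0[1:3]), c(mean_thickness = 0, max_height = 0,
                                   p99_height = 0))
  expect_false(hs0$covered)
  h <- matrix(0, 20, 20)
  h[10, 10] <- 1.2; h[10, 11] <- 0.6
  expect_equal(height_stats(as_grid(h))$max_height, 1.2)
})

test_that("porosity is the envelope void fraction with its boundary conventions", {
  expect_equal(porosity(as_grid(matrix(0.4, 8, 8))), 0)   # space-filling slab
  expect_equal(porosity(as_grid(matrix(0, 8, 8))), 1)     # uncovered region
  h <- matrix(0, 10, 10); h[, 1:5] <- 0.6                 # half-covering slab
  expect_equal(porosity(as_grid(h)), 0.5)
  # always within [0, 1] on random fields
  set.seed(22)
  for (i in 1:20) {
    p <- porosity(as_grid(matrix(runif(100, 0, 1.5), 10, 10)))
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("GLCM correlation handles canonical textures", {
  cb <- (outer(1:8, 1:8, `+`) %% 2) * 0.5                 # checkerboard
  expect_equal(glcm_correlation(cb, n_levels = 2L, offsets = list(c(0L, 1L))),
               -1)
  expect_true(is.na(glcm_correlation(matrix(0.3, 8, 8))))  # constant region
  expect_true(is.na(glcm_correlation(matrix(0, 8, 8))))
  expect_error(glcm_correlation(matrix(runif(4), 2, 2),
                                offsets = list(c(0L, 3L))), "offset")
  expect_error(glcm_correlation(cb, offsets = list(c(0L, 0L))), "non-zero")
  # perfectly correlated stripes along the offset direction
  stripes <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8)
  expect_gt(glcm_correlation(stripes, n_levels = 8L,
                             offsets = list(c(1L, 0L))), 0.9)
})

test_that("GLCM correlation equals the brute-force pair-enumeration oracle", {
  set.seed(23)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (i in 1:25) {
    nr <- sample(4:20, 1); nc <- sample(4:20, 1)
    h <- matrix(runif(nr * nc, 0, 1.2), nr, nc)
    nl <- sample(c(4L, 8L, 16L), 1)
    expect_equal(glcm_correlation(h, n_levels = nl, offsets = offs),
                 glcm_corr_brute(h, nl, offs), tolerance = 1e-10)
  }
})

test_that("moving-window metrics are translation invariant on a uniform slab", {
  g <- as_grid(matrix(0.5, 50, 400))   # 2 x 16 mm
  wm <- moving_window_metrics(g, profile = NULL, window_mm = 4, step_mm = 2)
  expect_gt(nrow(wm), 3)
  expect_true(all(abs(wm$volume_mm3 - wm$volume_mm3[1]) < 1e-9))
  expect_true(all(wm$coverage == 1))
  expect_true(all(wm$porosity == 0))
  expect_true(all(is.na(wm$textural_correlation)))  # constant windows
})

test_that("a window equal to the grid extent reproduces whole-region metrics", {
  set.seed(24)
  g <- as_grid(matrix(runif(50 * 100, 0, 1), 50, 100))
  wm <- moving_window_metrics(g, profile = NULL, window_mm = 4, step_mm = 2)
  expect_equal(nrow(wm), 1L)
  expect_equal(wm$volume_mm3, biovolume(g))
  expect_equal(wm$coverage, coverage(g))
  expect_equal(wm$porosity, porosity(g))
  expect_equal(wm$textural_correlation, glcm_correlation(g))
})

test_that("windows carry interpolated shear and per-window accrual", {
  set.seed(25)
  prof <- gen_hydraulic_profile(x_range = c(0, 0.02))
  g1 <- as_grid(matrix(0.2, 25, 500), day = 12L)   # 1 x 20 mm
  g2 <- as_grid(matrix(0.3, 25, 500), day = 15L)
  wm <- moving_window_metrics(g2, prof, window_mm = 10, step_mm = 5,
                              prev = g1)
  expect_true(all(is.finite(wm$tau_Pa)))
  expect_true(all(diff(wm$tau_Pa) > 0))
  area_mm2 <- 25 * 250 * 0.04^2
  expect_equal(wm$accrual_mm3_day, rep(area_mm2 * 0.1 / 3, nrow(wm)))
})
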