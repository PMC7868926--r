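test_that("uniform slab is all base and all-zero grid is all bare", {
  sm <- segment_landscape(as_grid(matrix(0.3, 30, 30)), local_window_mm = 0.8)
  expect_equal(unname(sm$fractions[c("f_bare", "f_trough", "f_base",
                                     "f_cluster")]), c(0, 0, 1, 0))
  sm0 <- segment_landscape(as_grid(matrix(0, 30, 30)), local_window_mm = 0.8)
  expect_equal(unname(sm0$fractions["f_bare"]), 1)
})

test_that("class fractions always sum to 1", {
  set.seed(31)
  for (i in 1:10) {
    h <- matrix(rexp(40 * 40, rate = 1 / 0.2), 40, 40)
    sm <- segment_landscape(as_grid(h), local_window_mm = 1)
    expect_equal(sum(sm$fractions[c("f_bare", "f_trough", "f_base",
                                    "f_cluster")]), 1)
  }
})

test_that("segmentation is invariant to global height rescaling", {
  set.seed(32)
  h <- matrix(rexp(30 * 30, rate = 1 / 0.3), 30, 30)
  sm1 <- segment_landscape(as_grid(h), local_window_mm = 1, h_min = 0.01)
  sm2 <- segment_landscape(as_grid(3 * h), local_window_mm = 1, h_min = 0.03)
  expect_identical(sm1$labels, sm2$labels)
})

test_that("a planted Gaussian cluster segments into one blob matching the rule-applied truth", {
  # single tall cluster on a thin base, planted by hand for full control
  base <- 0.1
  g <- as_grid(matrix(base, 80, 80) + {
    cc <- (1:80 - 40.5) * 0.04
    outer(exp(-cc^2 / (2 * 0.4^2)), exp(-cc^2 / (2 * 0.4^2)))
  })
  sm <- segment_landscape(g, local_window_mm = 3, h_min = 0.01)
  cl <- extract_clusters(sm, g)
  expect_equal(cl$abundance, 1L)
  expect_equal(sm$labels[40, 40], 3L)    # blob contains the peak
  # and the generator's independent rule application matches exactly
  gen2 <- gen_landscape(landscape_params(
    extent_m = c(0.012, 0.03), tau_range = c(0.04, 0.05),
    cluster_density_mm2 = 0.02, min_sep_mm = 4, sigma_mm = 0.5,
    carpet_mean_mm = 0, colony_density_mm2 = 0, noise_sd = 0,
    quantize = FALSE, clip = FALSE), seed = 34, truth_labels = TRUE,
    local_window_mm = 6)
  sm2 <- segment_landscape(gen2$grid, local_window_mm = 6, h_min = 0.01)
  expect_identical(sm2$labels, gen2$truth$labels)
})

test_that("cluster extraction recovers planted bumps, volumes and aspect ratios", {
  px <- 0.04
  h <- matrix(0, 200, 500)   # 8 x 20 mm, sparse so the local mean stays low
  add <- function(h, r0, c0, sr, sc, A) {
    rr <- (seq_len(nrow(h)) - r0) * px; cc <- (seq_len(ncol(h)) - c0) * px
    h + A * outer(exp(-rr^2 / (2 * sr^2)), exp(-cc^2 / (2 * sc^2)))
  }
  h <- add(h, 100, 125, 0.3, 0.3, 1.0)
  h <- add(h, 100, 375, 0.3, 0.6, 0.8)   # flow-elongated, 2x aspect
  g <- as_grid(h)
  sm <- segment_landscape(g, local_window_mm = 16, h_min = 0.01)
  cl <- extract_clusters(sm, g)
  expect_equal(cl$abundance, 2L)
  vols <- sort(cl$clusters$volume_mm3)
  truth <- sort(2 * pi * c(0.3 * 0.3 * 1.0, 0.3 * 0.6 * 0.8))
  expect_true(all(abs(vols - truth) / truth < 0.05))
  elong <- cl$clusters[which.max(cl$clusters$length_flow_mm), ]
  expect_equal(elong$horizontal_aspect, 2, tolerance = 0.15)
  # cumulative histogram bookkeeping
  expect_equal(cl$cumulative$n_ge, c(2L, 1L))
})

test_that("a flat carpet yields no clusters", {
  set.seed(35)
  h <- matrix(0.25, 60, 60) + matrix(rnorm(3600, 0, 0.005), 60, 60)
  sm <- segment_landscape(as_grid(pmax(h, 0)), local_window_mm = 2)
  cl <- extract_clusters(sm, as_grid(pmax(h, 0)))
  expect_equal(cl$abundance, 0L)
  expect_gt(sm$fractions["f_base"], 0.95)
})

test_that("morphotype direction: troughs dominate SFM scenes, base dominates FFM scenes", {
  sfm <- gen_landscape(landscape_params(
    extent_m = c(0.02, 0.05), tau_range = c(0.04, 0.05),
    cluster_density_mm2 = 0.015, min_sep_mm = 4, carpet_mean_mm = 0,
    colony_density_mm2 = 0.05, noise_sd = 0), seed = 36)
  sm_s <- segment_landscape(sfm$grid, local_window_mm = 12)
  expect_gt(sm_s$fractions["f_trough_merged"], sm_s$fractions["f_cluster"])
  ffm <- gen_landscape(landscape_params(
    extent_m = c(0.02, 0.05), tau_range = c(0.12, 0.13),
    cluster_density_mm2 = 0, carpet_mean_mm = 0.25, carpet_coverage = 0.95,
    corr_length_mm = 2, noise_sd = 0), seed = 37)
  sm_f <- segment_landscape(ffm$grid, local_window_mm = 12)
  expect_equal(names(which.max(sm_f$fractions[c("f_bare", "f_trough",
                                                "f_base", "f_cluster")])),
               "f_base")
})

test_that("8-connected labeling agrees with a flood-fill oracle", {
  set.seed(38)
  for (i in 1:8) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    mine <- biofilmscape:::.label8(mask)
    oracle <- flood_fill_label(mask)
    expect_equal(max(mine), max(oracle))
    expect_identical(mine > 0, oracle > 0)
    # identical partitions up to label permutation: component label pairs
    # must be in bijection
    pairs <- unique(cbind(mine[mask], oracle[mask]))
    expect_equal(nrow(pairs), max(oracle))
    expect_equal(length(unique(pairs[, 1])), max(oracle))
    expect_equal(length(unique(pairs[, 2])), max(oracle))
  }
})

test_that("speckle below the minimum area is discarded", {
  h <- matrix(0, 50, 50)
  h[25, 25] <- 1   # single-pixel spike: 0.0016 mm^2 < 0.01 mm^2
  g <- as_grid(h)
  sm <- segment_landscape(g, local_window_mm = 1.5, h_min = 0.01)
  expect_equal(extract_clusters(sm, g, min_area_mm2 = 0.01)$abundance, 0L)
  expect_equal(extract_clusters(sm, g, min_area_mm2 = 0.001)$abundance, 1L)
})
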