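mk_profile <- function(z, C, id = "p1", cond = "dark", mt = "SFM") {
  data.frame(profile_id = id, depth_mm = z, O2_umol_L = C,
             condition = cond, morphotype = mt,
             wall_distance_mm = NA_real_)
}

test_that("profile CSVs parse, re-zero to the surface, and round-trip", {
  d <- withr::local_tempdir()
  z <- seq(0, 0.5, by = 0.05)
  f1 <- file.path(d, "p1.csv")
  write.csv(data.frame(depth_mm = z + 0.2, O2_umol_L = 300 - 100 * z),
            f1, row.names = FALSE)
  ps <- parse_profiles(f1, list(list(profile_id = "p1", condition = "dark",
                                     morphotype = "SFM", surface_z_mm = 0.2)))
  expect_equal(ps$depth_mm, z, tolerance = 1e-12)
  # round trip through CSV preserves the set
  f2 <- file.path(d, "roundtrip.csv")
  write.csv(ps, f2, row.names = FALSE)
  ps2 <- oxygen_profile_set(read.csv(f2))
  expect_equal(ps2$O2_umol_L, ps$O2_umol_L)
  # unordered depths and missing condition are rejected
  f3 <- file.path(d, "bad.csv")
  write.csv(data.frame(depth_mm = c(0, 0.2, 0.1), O2_umol_L = 1),
            f3, row.names = FALSE)
  expect_error(parse_profiles(f3, list(list(condition = "dark",
                                            morphotype = "SFM"))),
               "increasing")
  expect_error(parse_profiles(f1, list(list(morphotype = "SFM"))),
               "condition")
})

test_that("surface estimation picks the steepest dark gradient", {
  z <- seq(-0.2, 0.5, by = 0.01)
  C <- 300 / (1 + exp((z - 0.1) / 0.05))   # steepest change at z = 0.1
  expect_lt(abs(estimate_surface(z, C) - 0.1), 0.02)
})

test_that("local gradients follow closed forms", {
  z <- seq(0, 0.5, by = 0.01)
  expect_equal(local_gradient(z, 300 - 100 * z), -100, tolerance = 1e-9)
  expect_lt(abs(local_gradient(z, rep(250, length(z)))), 1e-9)
  # quadratic diffusion-reaction profile: OLS slope over [z1, z2] equals the
  # analytic mean derivative -(R/D)(L - (z1+z2)/2) up to a curvature term.
  RD <- 1000; L <- 0.5
  C <- 300 - RD * (L * z - z^2 / 2)
  ols <- local_gradient(z, C, 0.05, 0.15)
  oracle <- unname(coef(lm(C[z >= 0.05 & z <= 0.15] ~ z[z >= 0.05 & z <= 0.15]))[2])
  expect_equal(ols, oracle, tolerance = 1e-10)
  expect_equal(ols, -RD * (L - 0.1), tolerance = 0.01 * RD * L)
  expect_error(local_gradient(c(0, 0.5), c(1, 2), 0.05, 0.15), "fewer than 2")
  # two-point mode
  expect_equal(local_gradient(z, 300 - 100 * z, method = "endpoints"), -100)
})

test_that("light:dark ratio is symmetric, scale invariant and guards zero gradients", {
  z <- seq(0, 0.5, by = 0.01)
  dark <- mk_profile(z, 300 - 1000 * (0.5 * z - z^2 / 2))
  light <- mk_profile(z, 300 + 1000 * (0.5 * z - z^2 / 2), cond = "light")
  expect_equal(light_dark_ratio(light, dark), 1, tolerance = 1e-10)
  # production twice consumption
  light2 <- mk_profile(z, 300 + 2000 * (0.5 * z - z^2 / 2), cond = "light")
  expect_equal(light_dark_ratio(light2, dark), 2, tolerance = 1e-10)
  # scale invariance
  darkc <- dark; darkc$O2_umol_L <- dark$O2_umol_L * 3.7
  lightc <- light; lightc$O2_umol_L <- light$O2_umol_L * 3.7
  expect_equal(light_dark_ratio(lightc, darkc),
               light_dark_ratio(light, dark), tolerance = 1e-12)
  flat <- mk_profile(z, rep(300, length(z)))
  expect_true(is.na(light_dark_ratio(light, flat)))
})

test_that("Brown-Forsythe statistic matches hand and library oracles", {
  g1 <- c(1, 2, 3, 4, 5); g2 <- c(3, 3, 3, 3, 3)
  r <- brown_forsythe_test(list(g1, g2))
  expect_equal(r$W, bf_oracle(list(g1, g2)), tolerance = 1e-10)
  # library cross-check (car's median-centered Levene test)
  lev <- car::leveneTest(c(g1, g2), factor(rep(1:2, each = 5)),
                         center = median)
  expect_equal(r$W, lev$`F value`[1], tolerance = 1e-10)
  expect_equal(r$p_value, lev$`Pr(>F)`[1], tolerance = 1e-10)
  # identical groups: W = 0, p = 1
  r0 <- brown_forsythe_test(list(g2, g2))
  expect_equal(r0$W, 0); expect_equal(r0$p_value, 1)
  # scale-shifted Gaussians are detected
  set.seed(61)
  r3 <- brown_forsythe_test(list(rnorm(50, 0, 3), rnorm(50, 0, 1)))
  expect_lt(r3$p_value, 0.01)
  # random inputs match the hand formula
  for (i in 1:10) {
    gs <- list(rnorm(sample(5:15, 1)), rnorm(sample(5:15, 1)),
               rnorm(sample(5:15, 1)))
    expect_equal(brown_forsythe_test(gs)$W, bf_oracle(gs), tolerance = 1e-10)
  }
})

test_that("Welch test matches the hand formula", {
  r <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-10)
  set.seed(62)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0.5)
    mine <- welch_test(a, b); hand <- welch_oracle(a, b)
    expect_equal(mine$t, hand$t, tolerance = 1e-10)
    expect_equal(mine$df, hand$df, tolerance = 1e-10)
    expect_equal(mine$p_value, hand$p, tolerance = 1e-10)
  }
  # degenerate equal constants
  r0 <- welch_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r0$t, 0); expect_equal(r0$p_value, 1)
  # strong shift is detected
  set.seed(63)
  expect_lt(welch_test(rnorm(30), rnorm(30, 5))$p_value, 0.001)
})

test_that("depth-binned comparison flags planted wall replenishment and skips thin bins", {
  ox <- suppressWarnings(gen_oxygen(oxygen_params(noise_sd = 3), seed = 64))
  st <- oxygen_profile_stats(ox$profiles)
  wc <- st$wall_compare
  planted <- wc$bin_lo_mm >= 0.1 & wc$bin_hi_mm <= 0.5 & !wc$skipped
  expect_true(all(wc$q_value[planted] < 0.01))
  # identical sets give flat p values
  z <- seq(0, 0.5, by = 0.01)
  set.seed(65)
  a <- mk_profile(z, 300 - 100 * z + rnorm(length(z)), id = "a")
  b <- mk_profile(z, 300 - 100 * z + rnorm(length(z)), id = "b")
  same <- grouped_depth_compare(rbind(a, a), rbind(a, a))
  expect_true(all(same$p_value[!same$skipped] > 0.99))
  # a bin populated on one side only is skipped with a note
  short <- mk_profile(seq(0, 0.25, by = 0.01), 300 - 100 * seq(0, 0.25, 0.01),
                      id = "s")
  gc <- grouped_depth_compare(rbind(a, b), rbind(short, short))
  expect_true(any(gc$skipped))
  expect_match(gc$note[gc$skipped][1], "skipped")
})
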