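test_that("landscape generation is deterministic under a fixed seed", {
  lp <- landscape_params(extent_m = c(0.012, 0.04))
  g1 <- gen_landscape(lp, seed = 71)
  g2 <- gen_landscape(lp, seed = 71)
  expect_identical(g1$grid$heights, g2$grid$heights)
  expect_identical(g1$truth$clusters, g2$truth$clusters)
  g3 <- gen_landscape(lp, seed = 72)
  expect_false(identical(g1$grid$heights, g3$grid$heights))
})

test_that("zero densities produce an all-zero DEM", {
  lp <- landscape_params(extent_m = c(0.008, 0.02), cluster_density_mm2 = 0,
                         carpet_mean_mm = 0, colony_density_mm2 = 0,
                         noise_sd = 0)
  g <- gen_landscape(lp, seed = 73)
  expect_true(all(g$grid$heights == 0))
})

test_that("generated heights honor the measurement model", {
  lp <- landscape_params(extent_m = c(0.01, 0.03), amp_meanlog = log(1.4),
                         cluster_density_mm2 = 0.05, min_sep_mm = 3,
                         clip_height = 0.6)
  g <- gen_landscape(lp, seed = 74)
  h <- g$grid$heights
  expect_true(all(h >= 0))
  expect_lte(max(h), 0.6 + 1e-12)
  # quantization: heights are integer multiples of the quantum
  expect_lt(max(abs(h / lp$z_quantum - round(h / lp$z_quantum))), 1e-6)
})

test_that("segmentation on a noiseless planted scene recovers the cluster count", {
  lp <- landscape_params(extent_m = c(0.02, 0.05), tau_range = c(0.04, 0.05),
                         cluster_density_mm2 = 0.003, min_sep_mm = 6,
                         sigma_mm = 0.35, amp_meanlog = log(1.3),
                         amp_sdlog = 0.1, carpet_mean_mm = 0,
                         colony_density_mm2 = 0, noise_sd = 0,
                         quantize = FALSE)
  gen <- gen_landscape(lp, seed = 76)
  n_true <- nrow(gen$truth$clusters)
  expect_gt(n_true, 1)
  sm <- segment_landscape(gen$grid, local_window_mm = 24, h_min = 0.01)
  cl <- extract_clusters(sm, gen$grid)
  expect_equal(cl$abundance, n_true)
  # volumes within 5 percent of the planted analytic volumes
  vols <- sort(cl$clusters$volume_mm3)
  truth <- sort(gen$truth$clusters$analytic_volume_mm3)
  expect_true(all(abs(vols - truth) / truth < 0.05))
})

test_that("time series bookkeeping matches the event log", {
  lp <- landscape_params(extent_m = c(0.012, 0.03), tau_range = c(0.04, 0.05),
                         cluster_density_mm2 = 0.03, min_sep_mm = 4,
                         sigma_mm = 0.4, carpet_mean_mm = 0,
                         colony_density_mm2 = 0, noise_sd = 0)
  # no events: negative growth stays at quantization scale
  ts0 <- gen_timeseries(lp, days = c(12, 15), detach_prob = 0,
                        displace_prob = 0, seed = 76)
  d0 <- series_displacement(ts0$series)
  qbound <- lp$z_quantum * prod(dim(ts0$series$grids[[1]]$heights)) * 0.04^2
  expect_lt(d0$negative_volume_mm3, qbound)
  expect_equal(nrow(ts0$truth$event_log), 0L)
  # forced detachment of every cluster with zero growth: total dV = -V
  ts1 <- gen_timeseries(lp, days = c(12, 15), doubling_days = Inf,
                        detach_prob = 1, displace_prob = 0, seed = 77)
  expect_true(all(ts1$truth$event_log$event == "detach"))
  d1 <- dem_difference(ts1$series$grids[[1]], ts1$series$grids[[2]])
  V <- sum(ts1$truth$clusters$analytic_volume_mm3)
  expect_equal(biovolume(ts1$series$grids[[1]]) -
                 biovolume(ts1$series$grids[[2]]), V, tolerance = 0.02)
  expect_equal(d1$negative_volume, V, tolerance = 0.02)
})

test_that("oxygen closed forms obey the diffusion-reaction balance", {
  p <- oxygen_params(noise_sd = 0, sdlog_sfm = 0, sdlog_ffm = 0,
                     ratio_sdlog = 0, n_sfm = 2L, n_ffm = 2L,
                     n_wall = 0L, n_core = 0L)
  ox <- gen_oxygen(p, seed = 78)
  prof <- ox$profiles
  dark <- prof[prof$profile_id == "SFM_01" & prof$condition == "dark" &
                 prof$depth_mm >= 0, ]
  # base concentration C(L) = C0 - (R/D) L^2 / 2 = 300 - 2080 * 0.125 = 40
  expect_equal(tail(dark$O2_umol_L, 1), 40, tolerance = 1e-9)
  ffm_dark <- prof[prof$profile_id == "FFM_01" & prof$condition == "dark" &
                     prof$depth_mm >= 0, ]
  expect_equal(tail(ffm_dark$O2_umol_L, 1), 178, tolerance = 1e-9)
  # discrete second difference equals (R/D) * dz^2 inside the biofilm
  dz <- p$dz_mm
  d2 <- diff(diff(dark$O2_umol_L))
  expect_lt(max(abs(d2 - p$RD_sfm * dz^2)), 1e-8)
  # balanced production: noiseless light:dark ratio is 1
  light <- prof[prof$profile_id == "SFM_01" & prof$condition == "light", ]
  expect_equal(light_dark_ratio(light, dark), 1, tolerance = 1e-9)
  # zero reaction gives a constant profile at C0
  ox0 <- gen_oxygen(oxygen_params(RD_sfm = 0, PD_sfm = 0, RD_ffm = 0,
                                  PD_ffm = 0, noise_sd = 0, sdlog_sfm = 0,
                                  sdlog_ffm = 0, ratio_sdlog = 0,
                                  n_sfm = 1L, n_ffm = 1L, n_wall = 0L,
                                  n_core = 0L), seed = 79)
  expect_true(all(ox0$profiles$O2_umol_L == 300))
})

test_that("parameters driving concentrations negative are truncated with a warning", {
  expect_warning(
    ox <- gen_oxygen(oxygen_params(RD_sfm = 6000, noise_sd = 0,
                                   sdlog_sfm = 0, sdlog_ffm = 0,
                                   ratio_sdlog = 0, n_sfm = 1L, n_ffm = 1L,
                                   n_wall = 0L, n_core = 0L), seed = 80),
    "truncated")
  expect_true(ox$truth$truncated)
  expect_true(all(ox$profiles$O2_umol_L >= 0))
})

test_that("SFM dark concentrations are more heterogeneous than FFM", {
  # anoxic truncation in some strongly respiring SFM profiles is expected
  ox <- suppressWarnings(gen_oxygen(seed = 81))
  p <- ox$profiles
  inb <- p[p$depth_mm >= 0 & is.na(p$wall_distance_mm), ]
  v_sfm <- var(inb$O2_umol_L[inb$morphotype == "SFM" & inb$condition == "dark"])
  v_ffm <- var(inb$O2_umol_L[inb$morphotype == "FFM" & inb$condition == "dark"])
  expect_gt(v_sfm, v_ffm)
})

test_that("the hydraulic profile generator spans the gradient endpoints", {
  p <- gen_hydraulic_profile()
  expect_equal(range(p$tau_Pa), c(0.04, 0.13))
  expect_equal(range(p$U_m_s), c(0.06, 0.13))
  expect_equal(range(p$Re), c(793, 1407))
  expect_true(all(diff(p$x_m) > 0))
})
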