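#' Parameters for the synthetic biofilm landscape generator
#'
#' Defines a ground-truthed emulation of a flume-grown phototrophic biofilm
#' landscape along a bed-shear gradient. Two morphotypes are blended by a
#' logistic weight in local shear stress: below the transition (`tau_star`)
#' a slow-flow morphotype (SFM) of tall, slightly flow-elongated Gaussian
#' clusters (lognormal amplitudes capped at 1.5 mm) over sparse small
#' colonies (<0.1 mm); above it a fast-flow morphotype (FFM) carpet built
#' from a thresholded, smoothed Gaussian random field of coalescing patches.
#' The measurement model mimics OCT artefacts: additive sensor noise, depth
#' clipping at the instrument ceiling, then height quantization.
#'
#' All arguments have defaults matching the emulated study conditions
#' (0.025 x 0.4 m extent, 40 um pixels, 2.18 um height quantum, shear
#' 0.04-0.13 Pa with the morphotype transition at 0.08 Pa, ~1.2 mm ceiling).
#'
#' @param extent_m `c(cross, streamwise)` extent in m.
#' @param pixel_size_mm lateral pixel size, mm.
#' @param tau_range shear stress at the two streamwise ends, Pa.
#' @param tau_star morphotype transition shear, Pa.
#' @param logistic_width logistic blending width in Pa.
#' @param cluster_density_mm2 SFM cluster density per mm^2 (applied to the
#'   SFM-weighted area).
#' @param amp_meanlog,amp_sdlog lognormal cluster amplitude parameters (mm).
#' @param amp_cap amplitude cap, mm.
#' @param sigma_mm cross-flow Gaussian radius of clusters, mm.
#' @param anisotropy streamwise/cross radius ratio (> 1 = flow-elongated).
#' @param min_sep_mm minimum center separation between clusters, mm.
#' @param edge_margin_mm keep cluster centers at least this far from the
#'   grid edge (default 4 cross-flow radii, so planted bumps lie fully
#'   inside the grid and their analytic volumes are valid ground truth).
#' @param colony_density_mm2,colony_amp_mm,colony_sigma_mm small-colony
#'   field in the troughs.
#' @param carpet_mean_mm FFM carpet mean thickness at the transition shear,
#'   mm. Patch tops are clamped at the 98th percentile of the thresholded
#'   field before scaling, so the carpet stays thin and plateau-like, well
#'   below cluster heights.
#' @param carpet_tau_slope relative increase of carpet thickness per unit of
#'   shear excess above `tau_star`, normalized to the upper end of
#'   `tau_range` (1 = carpet doubles between the transition and the outlet;
#'   emulates accrual increasing with shear above the threshold only).
#' @param corr_length_mm FFM carpet correlation length, mm.
#' @param carpet_coverage FFM carpet target coverage fraction.
#' @param noise_sd sensor noise standard deviation, mm.
#' @param z_quantum height quantum, mm.
#' @param clip_height instrument depth ceiling, mm.
#' @param quantize,clip toggles for the measurement model stages.
#' @return a `landscape_params` list.
#' @export
landscape_params <- function(extent_m = c(0.025, 0.4), pixel_size_mm = 0.040,
                             tau_range = c(0.04, 0.13), tau_star = 0.08,
                             logistic_width = 0.004,
                             cluster_density_mm2 = 0.012,
                             amp_meanlog = log(0.7), amp_sdlog = 0.35,
                             amp_cap = 1.5, sigma_mm = 0.8, anisotropy = 1.3,
                             min_sep_mm = 5, edge_margin_mm = NULL,
                             colony_density_mm2 = 0.05, colony_amp_mm = 0.05,
                             colony_sigma_mm = 0.1,
                             carpet_mean_mm = 0.15, corr_length_mm = 1.0,
                             carpet_coverage = 0.9, carpet_tau_slope = 1.0,
                             noise_sd = 0.002, z_quantum = 0.00218,
                             clip_height = 1.2, quantize = TRUE, clip = TRUE) {
  if (any(extent_m <= 0) || pixel_size_mm <= 0) stop("degenerate extent")
  if (diff(tau_range) <= 0) stop("tau_range must be increasing")
  if (is.null(edge_margin_mm)) edge_margin_mm <- 4 * sigma_mm * max(1, anisotropy)
  p <- as.list(environment())
  class(p) <- "landscape_params"
  p
}

# Linear shear ramp over the streamwise extent (x in mm from the inlet edge).
.tau_of_x <- function(params, x_mm) {
  L <- params$extent_m[2] * 1000
  params$tau_range[1] + (params$tau_range[2] - params$tau_range[1]) * x_mm / L
}

# SFM weight: 1 well below the transition shear, 0 well above.
.sfm_weight <- function(params, tau) {
  1 / (1 + exp((tau - params$tau_star) / params$logistic_width))
}

# Carpet thickness multiplier: flat up to the transition shear, then rising
# linearly with shear excess (accrual scales with shear above the threshold).
.carpet_ramp <- function(params, tau) {
  span <- max(params$tau_range[2] - params$tau_star, 1e-9)
  1 + params$carpet_tau_slope * pmax(tau - params$tau_star, 0) / span
}

# Place cluster centers uniformly with a minimum separation (dart throwing).
.place_clusters <- function(n_target, ny_mm, nx_mm, min_sep, margin = 0) {
  if (n_target <= 0L) return(cbind(x = numeric(0), y = numeric(0)))
  if (2 * margin >= min(nx_mm, ny_mm)) margin <- 0
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n_target && tries < 50L * n_target) {
    cand <- c(stats::runif(1, margin, nx_mm - margin),
              stats::runif(1, margin, ny_mm - margin))
    if (nrow(pts) == 0L ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_sep^2)
      pts <- rbind(pts, cand)
    tries <- tries + 1L
  }
  colnames(pts) <- c("x", "y")
  pts
}

# Add an anisotropic Gaussian bump evaluated on its +-4 sigma box.
.add_bump <- function(field, px, x_mm, y_mm, sx, sy, amp) {
  nr <- nrow(field); nc <- ncol(field)
  c0 <- max(1L, floor((x_mm - 4 * sx) / px) + 1L)
  c1 <- min(nc, ceiling((x_mm + 4 * sx) / px))
  r0 <- max(1L, floor((y_mm - 4 * sy) / px) + 1L)
  r1 <- min(nr, ceiling((y_mm + 4 * sy) / px))
  if (c0 > c1 || r0 > r1) return(field)
  xs <- ((c0:c1) - 0.5) * px
  ys <- ((r0:r1) - 0.5) * px
  bump <- amp * outer(exp(-(ys - y_mm)^2 / (2 * sy^2)),
                      exp(-(xs - x_mm)^2 / (2 * sx^2)))
  field[r0:r1, c0:c1] <- field[r0:r1, c0:c1] + bump
  field
}

# Gaussian random field by circular FFT smoothing of white noise,
# standardized to zero mean and unit variance.
.gaussian_field <- function(nr, nc, corr_px) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  kr <- stats::dnorm(c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)), sd = corr_px)
  kc <- stats::dnorm(c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)), sd = corr_px)
  K <- outer(kr, kc)
  K <- K / sum(K)
  g <- Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  (g - mean(g)) / stats::sd(g)
}

.carpet_field <- function(params, ny, nx) {
  if (params$carpet_mean_mm <= 0) return(matrix(0, ny, nx))
  g <- .gaussian_field(ny, nx, params$corr_length_mm / params$pixel_size_mm)
  thr <- stats::quantile(g, 1 - params$carpet_coverage)
  carpet <- pmax(g - thr, 0)
  pos <- carpet[carpet > 0]
  if (length(pos) > 0) carpet <- pmin(carpet, stats::quantile(pos, 0.98))
  carpet * (params$carpet_mean_mm / mean(carpet))
}

.measurement_model <- function(field, params) {
  h <- field
  if (params$noise_sd > 0)
    h <- h + matrix(stats::rnorm(length(h), 0, params$noise_sd),
                    nrow(h), ncol(h))
  h <- pmax(h, 0)
  if (params$clip) h <- pmin(h, params$clip_height)
  if (params$quantize) h <- round(h / params$z_quantum) * params$z_quantum
  h
}

#' Generate a ground-truthed synthetic biofilm landscape
#'
#' Builds the noiseless morphotype blend described in [landscape_params()],
#' applies the OCT measurement model, and records ground truth: the planted
#' clusters with their analytic volumes (`2 * pi * sigma_x * sigma_y * amp`
#' for a Gaussian cap), the noiseless field, and (optionally) the
#' cluster/trough classification obtained by applying the relative-threshold
#' rule to the noiseless field through an independent moving-average code
#' path (`stats::filter`), for checking the segmentation module.
#'
#' @param params a [landscape_params()].
#' @param seed integer RNG seed; the same seed reproduces the DEM
#'   bit-identically (Mersenne-Twister / inversion sampling).
#' @param day,flume_id metadata for the emitted [dem_grid()].
#' @param truth_labels if `TRUE`, compute reference threshold labels on the
#'   noiseless field (slow; intended for small test grids).
#' @param local_window_mm,k_hi,k_lo,h_min rule parameters for
#'   `truth_labels`.
#' @return list with `grid` (a [dem_grid()]) and `truth` (list: `clusters`
#'   data frame, `field` noiseless matrix, `tau` per-column shear,
#'   `weight` per-column SFM weight, `params`, `seed`, optional `labels`).
#' @export
gen_landscape <- function(params = landscape_params(), seed = 1L,
                          day = 15L, flume_id = "I", truth_labels = FALSE,
                          local_window_mm = 24, k_hi = 2, k_lo = 2,
                          h_min = 0.010) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  px <- params$pixel_size_mm
  ny <- max(1L, round(params$extent_m[1] * 1000 / px))
  nx <- max(1L, round(params$extent_m[2] * 1000 / px))
  ny_mm <- ny * px; nx_mm <- nx * px
  xs <- (seq_len(nx) - 0.5) * px
  tau <- .tau_of_x(params, xs)
  w <- .sfm_weight(params, tau)          # per-column SFM weight

  # SFM clusters: density applied to the SFM-weighted area
  area_sfm <- ny_mm * px * sum(w)
  n_clu <- stats::rpois(1, params$cluster_density_mm2 * area_sfm)
  pts <- .place_clusters(n_clu, ny_mm, nx_mm, params$min_sep_mm,
                         params$edge_margin_mm)
  sy <- params$sigma_mm; sx <- params$sigma_mm * params$anisotropy
  clusters <- data.frame(id = integer(0), x_mm = numeric(0), y_mm = numeric(0),
                         sigma_x_mm = numeric(0), sigma_y_mm = numeric(0),
                         amp_mm = numeric(0), analytic_volume_mm3 = numeric(0))
  sfm <- matrix(0, ny, nx)
  if (nrow(pts) > 0L) {
    amps <- pmin(stats::rlnorm(nrow(pts), params$amp_meanlog, params$amp_sdlog),
                 params$amp_cap)
    wc <- .sfm_weight(params, .tau_of_x(params, pts[, 1]))
    amps <- amps * wc                    # fade clusters out across the transition
    keep <- amps > 10 * params$z_quantum
    pts <- pts[keep, , drop = FALSE]; amps <- amps[keep]
    for (i in seq_len(nrow(pts)))
      sfm <- .add_bump(sfm, px, pts[i, 1], pts[i, 2], sx, sy, amps[i])
    clusters <- data.frame(id = seq_len(nrow(pts)), x_mm = pts[, 1],
                           y_mm = pts[, 2], sigma_x_mm = sx, sigma_y_mm = sy,
                           amp_mm = amps,
                           analytic_volume_mm3 = 2 * pi * sx * sy * amps)
  }
  # small colonies in the troughs
  n_col <- stats::rpois(1, params$colony_density_mm2 * area_sfm)
  if (n_col > 0L) {
    cx <- stats::runif(n_col, 0, nx_mm); cy <- stats::runif(n_col, 0, ny_mm)
    ca <- stats::runif(n_col, 0.3, 1) * params$colony_amp_mm *
      .sfm_weight(params, .tau_of_x(params, cx))
    for (i in seq_len(n_col))
      sfm <- .add_bump(sfm, px, cx[i], cy[i], params$colony_sigma_mm,
                       params$colony_sigma_mm, ca[i])
  }

  # FFM carpet: thresholded correlated field, scaled to the target mean
  carpet <- .carpet_field(params, ny, nx)

  # cluster amplitudes are already SFM-weighted at their centers
  field <- sfm + sweep(carpet, 2L, (1 - w) * .carpet_ramp(params, tau), `*`)
  heights <- .measurement_model(field, params)
  grid <- dem_grid(heights, pixel_size_xy = px, z_quantum = params$z_quantum,
                   x_origin = 0, day = day, flume_id = flume_id,
                   clip_height = params$clip_height)
  truth <- list(clusters = clusters, field = field, tau = tau, weight = w,
                params = params, seed = seed)
  if (truth_labels)
    truth$labels <- .reference_labels(field, px, local_window_mm, k_hi, k_lo,
                                      h_min)
  list(grid = grid, truth = truth)
}

# Reference threshold labels computed with stats::filter moving averages —
# a deliberately different code path from the package's integral-image one.
.reference_labels <- function(field, px, local_window_mm, k_hi, k_lo, h_min) {
  win <- 2L * (round(local_window_mm / px) %/% 2L) + 1L   # odd, centered
  kern <- rep(1, win)
  smooth1 <- function(m) {
    s <- apply(m, 2, function(col) stats::filter(col, kern, sides = 2))
    t(apply(t(s), 2, function(row) stats::filter(row, kern, sides = 2)))
  }
  num <- smooth1(field)
  cnt <- smooth1(matrix(1, nrow(field), ncol(field)))
  # stats::filter drops the window edge; fall back to edge-truncated means there
  lm_ <- num / cnt
  na <- !is.finite(lm_)
  if (any(na)) {
    bm <- .box_mean(field, win %/% 2L)
    lm_[na] <- bm[na]
  }
  labels <- matrix(2L, nrow(field), ncol(field))
  labels[field >= k_hi * lm_] <- 3L
  labels[field <= lm_ / k_lo] <- 1L
  labels[field < h_min] <- 0L
  labels
}

#' Generate a growth time series with detachment and displacement events
#'
#' Starts from the cluster and carpet layout of [gen_landscape()] and plays
#' it backwards/forwards in time: amplitudes grow exponentially (doubling
#' every `doubling_days`), reaching the planted values on the final day. At
#' each acquisition interval every SFM cluster independently either sloughs
#' off (probability `detach_prob`), is pushed downstream by `shift_px`
#' pixels (probability `displace_prob`), or grows in place; the carpet grows
#' without events. All events are recorded in an event log.
#'
#' @param params a [landscape_params()].
#' @param days acquisition days (default 3-day intervals to day 15).
#' @param doubling_days biovolume amplitude doubling time, days.
#' @param detach_prob,displace_prob per-cluster per-interval event
#'   probabilities.
#' @param shift_px downstream shift per displacement event, pixels.
#' @param seed RNG seed.
#' @param flume_id metadata for the series.
#' @return list with `series` (a [dem_series()]) and `truth` (planted
#'   clusters, per-day states, `event_log` data frame with columns `day`,
#'   `cluster_id`, `event`, `shift_px`, plus `params`, `seed`).
#' @export
gen_timeseries <- function(params = landscape_params(),
                           days = c(0, 3, 6, 9, 12, 15), doubling_days = 3,
                           detach_prob = 0.05, displace_prob = 0.10,
                           shift_px = 10L, seed = 1L, flume_id = "I") {
  stopifnot(length(days) >= 2L, all(diff(days) > 0))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  px <- params$pixel_size_mm
  ny <- max(1L, round(params$extent_m[1] * 1000 / px))
  nx <- max(1L, round(params$extent_m[2] * 1000 / px))
  ny_mm <- ny * px; nx_mm <- nx * px
  xs <- (seq_len(nx) - 0.5) * px
  tau <- .tau_of_x(params, xs)
  w <- .sfm_weight(params, tau)

  area_sfm <- ny_mm * px * sum(w)
  n_clu <- stats::rpois(1, params$cluster_density_mm2 * area_sfm)
  pts <- .place_clusters(n_clu, ny_mm, nx_mm, params$min_sep_mm,
                         params$edge_margin_mm)
  sy <- params$sigma_mm; sx <- params$sigma_mm * params$anisotropy
  amps <- if (nrow(pts) > 0L)
    pmin(stats::rlnorm(nrow(pts), params$amp_meanlog, params$amp_sdlog),
         params$amp_cap) *
      .sfm_weight(params, .tau_of_x(params, pts[, 1])) else numeric(0)
  keep <- amps > 10 * params$z_quantum
  pts <- pts[keep, , drop = FALSE]; amps <- amps[keep]
  ncl <- nrow(pts)

  carpet <- .carpet_field(params, ny, nx)
  carpet <- sweep(carpet, 2L, (1 - w) * .carpet_ramp(params, tau), `*`)

  state_x <- pts[, 1]; state_y <- pts[, 2]; alive <- rep(TRUE, ncl)
  event_log <- data.frame(day = integer(0), cluster_id = integer(0),
                          event = character(0), shift_px = integer(0))
  states <- list()
  grids <- vector("list", length(days))
  tmax <- max(days)
  for (k in seq_along(days)) {
    d <- days[k]
    if (k > 1L && ncl > 0L) {
      for (i in which(alive)) {
        u <- stats::runif(1)
        if (u < detach_prob) {
          alive[i] <- FALSE
          event_log <- rbind(event_log, data.frame(
            day = d, cluster_id = i, event = "detach", shift_px = 0L))
        } else if (u < detach_prob + displace_prob) {
          state_x[i] <- state_x[i] + shift_px * px
          event_log <- rbind(event_log, data.frame(
            day = d, cluster_id = i, event = "displace", shift_px = shift_px))
        }
      }
    }
    scale <- 2^((d - tmax) / doubling_days)
    field <- carpet * scale
    for (i in which(alive))
      field <- .add_bump(field, px, state_x[i], state_y[i], sx, sy,
                         amps[i] * scale)
    states[[k]] <- data.frame(day = d, cluster_id = seq_len(ncl),
                              x_mm = state_x, y_mm = state_y,
                              amp_mm = amps * scale, alive = alive)
    heights <- .measurement_model(field, params)
    grids[[k]] <- dem_grid(heights, pixel_size_xy = px,
                           z_quantum = params$z_quantum, x_origin = 0,
                           day = d, flume_id = flume_id,
                           clip_height = params$clip_height)
  }
  truth <- list(
    clusters = if (ncl > 0L) data.frame(
      id = seq_len(ncl), x_mm = pts[, 1], y_mm = pts[, 2],
      sigma_x_mm = sx, sigma_y_mm = sy, amp_mm = amps,
      analytic_volume_mm3 = 2 * pi * sx * sy * amps) else NULL,
    states = do.call(rbind, states), event_log = event_log,
    params = params, days = days, seed = seed)
  list(series = dem_series(grids), truth = truth)
}

#' Generate a tabulated hydraulic profile
#'
#' Linear ramps of mean velocity, bed shear stress and Reynolds number over
#' the streamwise extent; defaults reproduce the emulated flume gradient
#' (0.06-0.13 m/s, 0.04-0.13 Pa, Re 793-1407 over 0.4 m).
#'
#' @param n number of table rows.
#' @param x_range streamwise range, m.
#' @param U_range,tau_range,Re_range endpoint values.
#' @return a [hydraulic_profile()].
#' @export
gen_hydraulic_profile <- function(n = 50L, x_range = c(0, 0.4),
                                  U_range = c(0.06, 0.13),
                                  tau_range = c(0.04, 0.13),
                                  Re_range = c(793, 1407)) {
  x <- seq(x_range[1], x_range[2], length.out = n)
  lin <- function(r) r[1] + (r[2] - r[1]) * (x - x_range[1]) / diff(x_range)
  hydraulic_profile(data.frame(x_m = x, U_m_s = lin(U_range),
                               tau_Pa = lin(tau_range), Re = lin(Re_range)))
}
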