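#' Parameters for the synthetic oxygen microprofile generator
#'
#' Closed-form steady-state diffusion-reaction profiles through a biofilm of
#' thickness `L` with zero-order volumetric reaction, a fixed surface
#' concentration `C0` and a no-flux base:
#' dark (net consumption R): `C(z) = C0 - (R/D) (L z - z^2 / 2)`;
#' light (net production P): `C(z) = C0 + (P/D) (L z - z^2 / 2)`,
#' for depth `0 <= z <= L`; above the surface the concentration is the bulk
#' value `C0`. The dark reaction strengths default to values whose base
#' concentrations `C(L) = C0 - (R/D) L^2 / 2` reach 40 umol/L in the
#' slow-flow morphotype and 178 umol/L in the fast-flow morphotype; light
#' production defaults to `P = R` (balanced net fluxes, light:dark gradient
#' ratios around 1). Per-profile lognormal jitter of the reaction strength
#' is wider in the SFM than the FFM, emulating its more heterogeneous
#' micro-niches.
#'
#' Wall-replenishment variants add a positive oxygen offset that decays with
#' lateral distance from the cluster side wall (length scale `wall_lambda_mm`)
#' and ramps in over the first 0.1 mm of depth — the advective supply of
#' oxygen through trough-facing cluster walls.
#'
#' @param C0 bulk/surface concentration, umol/L.
#' @param L_mm biofilm thickness, mm.
#' @param RD_sfm,RD_ffm dark reaction strength (R/D), umol L^-1 mm^-2.
#' @param PD_sfm,PD_ffm light net production strength (P/D); default equal
#'   to the dark strengths.
#' @param sdlog_sfm,sdlog_ffm per-profile lognormal jitter of the reaction
#'   strength.
#' @param ratio_sdlog extra lognormal jitter of the light:dark strength
#'   ratio around 1.
#' @param n_sfm,n_ffm number of profile locations per morphotype.
#' @param dz_mm depth sampling step, mm.
#' @param z_above_mm extent sampled above the surface, mm.
#' @param noise_sd sensor noise SD, umol/L.
#' @param n_wall,n_core wall-replenishment profiles (dark, SFM) near the
#'   cluster wall and in the core.
#' @param wall_sdlog reaction-strength jitter within the wall/core transect
#'   groups; smaller than `sdlog_sfm` because these profiles cross the same
#'   cluster population, whose respiration varies less than the whole SFM.
#' @param wall_delta offset amplitude at the wall, umol/L.
#' @param wall_lambda_mm lateral decay length of the wall offset, mm.
#' @param wall_dist_mm,core_dist_mm tagged wall distances of the two groups.
#' @return an `oxygen_params` list.
#' @export
oxygen_params <- function(C0 = 300, L_mm = 0.5, RD_sfm = 2080, RD_ffm = 976,
                          PD_sfm = RD_sfm, PD_ffm = RD_ffm,
                          sdlog_sfm = 0.30, sdlog_ffm = 0.10,
                          ratio_sdlog = 0.08, n_sfm = 35L, n_ffm = 27L,
                          dz_mm = 0.01, z_above_mm = 0.10, noise_sd = 3,
                          n_wall = 8L, n_core = 8L, wall_sdlog = 0.05,
                          wall_delta = 60,
                          wall_lambda_mm = 0.3, wall_dist_mm = 0.1,
                          core_dist_mm = 2.0) {
  stopifnot(L_mm > 0, dz_mm > 0, C0 > 0)
  p <- as.list(environment())
  class(p) <- "oxygen_params"
  p
}

# Closed form on a depth grid; rate > 0 consumes (dark), rate < 0 produces.
.o2_closed_form <- function(z, C0, L, rate_over_D) {
  C <- ifelse(z < 0, C0, C0 - rate_over_D * (L * z - z^2 / 2))
  C
}

#' Generate a ground-truthed set of oxygen microprofiles
#'
#' Emits paired light/dark profiles per location for both morphotypes, plus
#' wall/core dark profile groups within SFM clusters, with the closed forms
#' and per-profile parameters recorded as ground truth. Concentrations that
#' would go negative are truncated at 0 with a warning and a truth flag.
#'
#' @param params an [oxygen_params()].
#' @param seed RNG seed.
#' @return list with `profiles` (an [oxygen_profile_set()]) and `truth`
#'   (per-profile data frame of closed-form parameters, `params`, `seed`,
#'   `truncated` flag).
#' @export
gen_oxygen <- function(params = oxygen_params(), seed = 1L) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  z <- seq(-params$z_above_mm, params$L_mm, by = params$dz_mm)
  truncated <- FALSE
  rows <- list(); truth_rows <- list()
  emit <- function(id, condition, morphotype, rate_over_D, wall_distance,
                   offset = 0) {
    C <- .o2_closed_form(z, params$C0, params$L_mm, rate_over_D) + offset
    if (any(C < 0)) { truncated <<- TRUE; C <- pmax(C, 0) }
    if (params$noise_sd > 0)
      C <- pmax(C + stats::rnorm(length(C), 0, params$noise_sd), 0)
    rows[[length(rows) + 1L]] <<- data.frame(
      profile_id = id, depth_mm = z, O2_umol_L = C, condition = condition,
      morphotype = morphotype, wall_distance_mm = wall_distance)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      profile_id = id, condition = condition, morphotype = morphotype,
      rate_over_D = rate_over_D, wall_distance_mm = wall_distance,
      wall_offset = offset)
  }
  for (mt in c("SFM", "FFM")) {
    n <- if (mt == "SFM") params$n_sfm else params$n_ffm
    RD <- if (mt == "SFM") params$RD_sfm else params$RD_ffm
    PD <- if (mt == "SFM") params$PD_sfm else params$PD_ffm
    sdl <- if (mt == "SFM") params$sdlog_sfm else params$sdlog_ffm
    for (i in seq_len(n)) {
      m <- stats::rlnorm(1, 0, sdl)
      r <- stats::rlnorm(1, 0, params$ratio_sdlog)
      id <- sprintf("%s_%02d", mt, i)
      emit(id, "dark", mt, RD * m, NA_real_)
      emit(id, "light", mt, -PD * m * r, NA_real_)
    }
  }
  # wall vs core dark profiles inside SFM clusters
  ramp <- pmin(pmax(z, 0) / 0.1, 1)
  for (i in seq_len(params$n_wall)) {
    m <- stats::rlnorm(1, 0, params$wall_sdlog)
    off <- params$wall_delta *
      exp(-params$wall_dist_mm / params$wall_lambda_mm) * ramp
    emit(sprintf("SFM_wall_%02d", i), "dark", "SFM", params$RD_sfm * m,
         params$wall_dist_mm, offset = off)
  }
  for (i in seq_len(params$n_core)) {
    m <- stats::rlnorm(1, 0, params$wall_sdlog)
    off <- params$wall_delta *
      exp(-params$core_dist_mm / params$wall_lambda_mm) * ramp
    emit(sprintf("SFM_core_%02d", i), "dark", "SFM", params$RD_sfm * m,
         params$core_dist_mm, offset = off)
  }
  if (truncated)
    warning("some closed-form concentrations were negative and truncated at 0")
  list(profiles = oxygen_profile_set(do.call(rbind, rows)),
       truth = list(profiles = do.call(rbind, truth_rows), params = params,
                    seed = seed, truncated = truncated))
}
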