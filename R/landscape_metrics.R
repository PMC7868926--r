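#' Biofilm volume over a region
#'
#' Integrates the DEM: `sum(heights) * pixel_size^2` over the region pixels,
#' in mm^3. Additive over disjoint regions.
#'
#' @param grid a [dem_grid()].
#' @param region `NULL` for the whole grid, or `c(r1, r2, c1, c2)` (1-based,
#'   inclusive pixel rectangle).
#' @return volume in mm^3.
#' @export
biovolume <- function(grid, region = NULL) {
  h <- .submat(grid$heights, region)
  sum(h) * grid$pixel_size_xy^2
}

#' Substrate coverage over a region
#'
#' Fraction of region pixels whose thickness reaches the detection threshold
#' `h_min`. The default threshold (0.010 mm, about five height quanta) sits
#' above quantization noise but below the smallest colonies of interest
#' (<0.1 mm).
#'
#' @inheritParams biovolume
#' @param h_min detection threshold, mm.
#' @return coverage fraction in \[0, 1\].
#' @export
coverage <- function(grid, region = NULL, h_min = 0.010) {
  stopifnot(h_min >= 0)
  h <- .submat(grid$heights, region)
  mean(h >= h_min)
}

#' Thickness statistics over covered pixels
#'
#' Mean thickness, maximum and 99th-percentile height over pixels at or
#' above the detection threshold. If no pixel is covered all three are 0 and
#' `covered` is `FALSE`.
#'
#' @inheritParams coverage
#' @return list with `mean_thickness`, `max_height`, `p99_height` (mm) and
#'   logical `covered`.
#' @export
height_stats <- function(grid, region = NULL, h_min = 0.010) {
  h <- .submat(grid$heights, region)
  cov <- h[h >= h_min]
  if (length(cov) == 0L)
    return(list(mean_thickness = 0, max_height = 0, p99_height = 0,
                covered = FALSE))
  list(mean_thickness = mean(cov), max_height = max(cov),
       p99_height = unname(stats::quantile(cov, 0.99)), covered = TRUE)
}

#' Landscape porosity of a region
#'
#' Void fraction of the envelope box bounding the biofilm surface:
#' `1 - volume / (region_area * p99_height)`, where the envelope height is
#' the 99th percentile of covered-pixel thickness (robust to single clipped
#' spikes). A fully space-filling slab has porosity 0; an uncovered region
#' is defined as porosity 1. This is a surface-DEM envelope definition: a
#' volumetric biomass porosity is not computable from a DEM.
#'
#' @inheritParams coverage
#' @return porosity fraction in \[0, 1\].
#' @export
porosity <- function(grid, region = NULL, h_min = 0.010) {
  hs <- height_stats(grid, region, h_min)
  if (!hs$covered || hs$p99_height <= 0) return(1)
  h <- .submat(grid$heights, region)
  vol <- sum(h) * grid$pixel_size_xy^2
  env <- length(h) * grid$pixel_size_xy^2 * hs$p99_height
  min(max(1 - vol / env, 0), 1)
}

#' Haralick textural correlation of a region
#'
#' Quantizes region heights to `n_levels` equal bins over `[0, max]`, builds
#' a symmetric, normalized gray-level co-occurrence matrix (GLCM) for each
#' pixel offset, and returns the mean Haralick correlation
#' `sum_ij (i - mu)(j - mu) p(i,j) / sigma^2` across offsets. Textural
#' correlation is a proxy for spatial aggregation of biomass: aggregated
#' cluster-and-trough landscapes score high, spatially uncorrelated ones
#' near 0. Returns `NA` (undefined) for constant regions, where the
#' correlation has zero variance.
#'
#' @inheritParams biovolume
#' @param n_levels number of gray levels (>= 2).
#' @param offsets list of integer `c(dr, dc)` pixel displacements.
#' @return mean correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
glcm_correlation <- function(grid, region = NULL, n_levels = 64L,
                             offsets = list(c(0L, 1L), c(1L, 0L),
                                            c(1L, 1L), c(1L, -1L))) {
  stopifnot(n_levels >= 2L, length(offsets) >= 1L)
  h <- if (inherits(grid, "dem_grid")) .submat(grid$heights, region)
       else .submat(as.matrix(grid), region)
  if (any(vapply(offsets, function(o) all(o == 0L), logical(1))))
    stop("offsets must be non-zero")
  if (any(vapply(offsets, function(o)
    abs(o[1]) >= nrow(h) || abs(o[2]) >= ncol(h), logical(1))))
    stop("region smaller than offset")
  q <- .quantize_levels(h, n_levels)
  vals <- vapply(offsets, function(o) .glcm_corr_one(q, n_levels, o[1], o[2]),
                 numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Map heights to 1..n_levels over [0, max(h)]; a constant region maps to 1.
.quantize_levels <- function(h, n_levels) {
  mx <- max(h)
  if (mx <= 0) return(matrix(1L, nrow(h), ncol(h)))
  pmin(floor(h / mx * n_levels) + 1L, as.integer(n_levels))
}

.glcm_corr_one <- function(q, L, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  a <- q[r1:r2, c1:c2, drop = FALSE]
  b <- q[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
  cnt <- tabulate((as.vector(a) - 1L) * L + as.vector(b), nbins = L * L)
  P <- matrix(cnt, L, L, byrow = TRUE)
  P <- P + t(P)                       # symmetric GLCM
  p <- P / sum(P)
  pi_ <- rowSums(p)
  lev <- seq_len(L)
  mu <- sum(lev * pi_)
  s2 <- sum((lev - mu)^2 * pi_)
  if (s2 <= .Machine$double.eps) return(NA_real_)
  (sum(tcrossprod(lev) * p) - mu^2) / s2
}

#' Moving-window landscape metrics along the shear gradient
#'
#' Slides a window of `window_mm` edge length (spanning the full
#' cross-section) along the streamwise axis in steps of `step_mm` and
#' computes, per window: biovolume, coverage, thickness statistics,
#' porosity and textural correlation, plus the bed shear stress interpolated
#' from the hydraulic profile at the window center. If an earlier-day grid
#' `prev` is supplied, the per-window accrual rate
#' `(V(day) - V(prev day)) / (day - prev day)` is added.
#'
#' @param grid a [dem_grid()] (typically the mature landscape).
#' @param profile a [hydraulic_profile()], or `NULL` to omit shear values.
#' @param window_mm window edge length, mm (default 24).
#' @param step_mm window stride, mm (default 2; strides much smaller than
#'   the edge give smooth curves but spatially overlapping, autocorrelated
#'   rows — see [fit_segmented()] for the inference consequence).
#' @param h_min detection threshold, mm.
#' @param prev optional earlier [dem_grid()] with identical geometry, for
#'   accrual rates.
#' @param n_levels,offsets GLCM settings, see [glcm_correlation()].
#' @return data frame (`window_metrics`) with one row per window position:
#'   `center_x_m`, `tau_Pa`, `volume_mm3`, `coverage`, `mean_thickness_mm`,
#'   `max_height_mm`, `p99_height_mm`, `porosity`, `textural_correlation`,
#'   and `accrual_mm3_day` when `prev` is given.
#' @export
moving_window_metrics <- function(grid, profile = NULL, window_mm = 24,
                                  step_mm = 2, h_min = 0.010, prev = NULL,
                                  n_levels = 64L,
                                  offsets = list(c(0L, 1L), c(1L, 0L),
                                                 c(1L, 1L), c(1L, -1L))) {
  px <- grid$pixel_size_xy
  nc <- ncol(grid$heights)
  win_px <- max(2L, round(window_mm / px))
  step_px <- max(1L, round(step_mm / px))
  if (win_px > nc) stop("window larger than grid streamwise extent")
  starts <- seq.int(1L, nc - win_px + 1L, by = step_px)
  if (!is.null(prev)) {
    if (!identical(dim(prev$heights), dim(grid$heights)))
      stop("prev grid geometry mismatch")
    if (prev$day >= grid$day) stop("prev must be an earlier day")
  }
  rows <- lapply(starts, function(s) {
    region <- c(1L, nrow(grid$heights), s, s + win_px - 1L)
    hs <- height_stats(grid, region, h_min)
    center_x <- grid$x_origin + (s - 1 + win_px / 2) * px / 1000
    tau <- NA_real_
    if (!is.null(profile)) {
      rng <- range(profile$x_m)
      if (center_x >= rng[1] && center_x <= rng[2])
        tau <- shear_profile_lookup(profile, center_x)$tau_Pa
    }
    data.frame(
      center_x_m = center_x, tau_Pa = tau,
      volume_mm3 = biovolume(grid, region),
      coverage = coverage(grid, region, h_min),
      mean_thickness_mm = hs$mean_thickness,
      max_height_mm = hs$max_height,
      p99_height_mm = hs$p99_height,
      porosity = porosity(grid, region, h_min),
      textural_correlation = glcm_correlation(grid, region, n_levels, offsets),
      accrual_mm3_day = if (is.null(prev)) NA_real_ else
        (biovolume(grid, region) - biovolume(prev, region)) /
          (grid$day - prev$day))
  })
  out <- do.call(rbind, rows)
  if (is.null(prev)) out$accrual_mm3_day <- NULL
  class(out) <- c("window_metrics", "data.frame")
  out
}
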