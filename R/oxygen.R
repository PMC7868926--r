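#' Oxygen microprofile set
#'
#' A validated long-format table of oxygen microprofiles: one row per sensor
#' reading, with depth in mm relative to the biofilm surface (negative =
#' above the surface, in the water column) and concentration in umol/L.
#' Each profile is tagged with a light/dark condition and a morphotype
#' (`SFM` = slow-flow cluster-and-trough, `FFM` = fast-flow carpet);
#' `wall_distance_mm` (lateral distance from the nearest cluster side wall)
#' is optional.
#'
#' @param df data frame with columns `profile_id`, `depth_mm`, `O2_umol_L`,
#'   `condition` (`"light"`/`"dark"`), `morphotype`, and optionally
#'   `wall_distance_mm`.
#' @return an `oxygen_profile_set` data frame.
#' @export
oxygen_profile_set <- function(df) {
  need <- c("profile_id", "depth_mm", "O2_umol_L", "condition", "morphotype")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (any(is.na(df$condition)) || !all(df$condition %in% c("light", "dark")))
    stop("condition must be 'light' or 'dark' for every reading")
  if (any(!is.finite(df$O2_umol_L)) || any(df$O2_umol_L < 0))
    stop("concentrations must be finite and >= 0")
  key <- paste(df$profile_id, df$condition)
  for (id in unique(key)) {
    z <- df$depth_mm[key == id]
    if (any(diff(z) <= 0))
      stop("depths must be strictly increasing within profile ", id)
  }
  class(df) <- c("oxygen_profile_set", "data.frame")
  df
}

#' Parse oxygen microprofile CSV files
#'
#' Each file needs columns `depth_mm` and `O2_umol_L`; `profile_id`,
#' `condition`, `morphotype`, `wall_distance_mm` and `surface_z_mm` may be
#' columns or supplied per-file through `metadata` (a list of named lists,
#' one per file, recycled if length 1). When a surface position
#' `surface_z_mm` is available, depths are re-zeroed so 0 is the biofilm
#' surface.
#'
#' @param files character vector of CSV paths.
#' @param metadata list of per-file metadata lists.
#' @return an [oxygen_profile_set()].
#' @export
parse_profiles <- function(files, metadata = list(list())) {
  if (length(metadata) == 1L) metadata <- rep(metadata, length(files))
  stopifnot(length(metadata) == length(files))
  parts <- lapply(seq_along(files), function(i) {
    d <- utils::read.csv(files[i])
    stopifnot(all(c("depth_mm", "O2_umol_L") %in% names(d)))
    m <- metadata[[i]]
    for (k in c("profile_id", "condition", "morphotype", "wall_distance_mm"))
      if (!is.null(m[[k]])) d[[k]] <- m[[k]]
    if (is.null(d$profile_id)) d$profile_id <- basename(files[i])
    if (is.null(d$condition)) stop("missing condition for ", files[i])
    if (is.null(d$morphotype)) stop("missing morphotype for ", files[i])
    surf <- if (!is.null(m$surface_z_mm)) m$surface_z_mm else
      if (!is.null(d$surface_z_mm)) d$surface_z_mm[1] else NULL
    if (!is.null(surf)) d$depth_mm <- d$depth_mm - surf
    d$surface_z_mm <- NULL
    if (is.null(d$wall_distance_mm)) d$wall_distance_mm <- NA_real_
    d
  })
  oxygen_profile_set(do.call(rbind, parts))
}

#' Estimate the biofilm surface position from a dark profile
#'
#' When no surface position is recorded, the surface is taken as the depth
#' of the steepest concentration change (maximum `|dC/dz|` by first
#' differences) in the dark profile, where respiration makes the gradient
#' sharpest.
#'
#' @param depth_mm,O2_umol_L profile vectors (depth increasing).
#' @return estimated surface depth, mm (midpoint of the steepest interval).
#' @export
estimate_surface <- function(depth_mm, O2_umol_L) {
  stopifnot(length(depth_mm) >= 3L, all(diff(depth_mm) > 0))
  g <- abs(diff(O2_umol_L) / diff(depth_mm))
  i <- which.max(g)
  (depth_mm[i] + depth_mm[i + 1L]) / 2
}

#' Local oxygen gradient over a depth window
#'
#' Ordinary least-squares slope of concentration against depth over the
#' window `[z1, z2]` (default 0.05-0.15 mm below the surface), in
#' umol L^-1 mm^-1. OLS over the window is robust to sensor noise; set
#' `method = "endpoints"` for a plain two-point difference.
#'
#' @param depth_mm,O2_umol_L profile vectors.
#' @param z1,z2 depth window bounds, mm.
#' @param method `"ols"` (default) or `"endpoints"`.
#' @return slope, umol L^-1 mm^-1 (negative = decreasing into the biofilm).
#' @export
local_gradient <- function(depth_mm, O2_umol_L, z1 = 0.05, z2 = 0.15,
                           method = c("ols", "endpoints")) {
  method <- match.arg(method)
  sel <- depth_mm >= z1 & depth_mm <= z2
  if (sum(sel) < 2L) stop("fewer than 2 readings in the depth window")
  z <- depth_mm[sel]; c_ <- O2_umol_L[sel]
  if (method == "endpoints")
    return((c_[length(c_)] - c_[1]) / (z[length(z)] - z[1]))
  unname(stats::coef(stats::lm(c_ ~ z))[2])
}

#' Light:dark oxygen gradient ratio
#'
#' `|slope_light| / |slope_dark|` over the same depth window at the same
#' location: a proxy for net autotrophic versus heterotrophic aerial oxygen
#' fluxes (ratio ~1 means production balances consumption). Undefined (`NA`)
#' when the dark gradient is zero. Scale-invariant: multiplying all
#' concentrations by a constant leaves it unchanged.
#'
#' @param light,dark data frames with `depth_mm`, `O2_umol_L` (and matching
#'   `profile_id`/location if present).
#' @inheritParams local_gradient
#' @return ratio (>= 0) or `NA_real_`.
#' @export
light_dark_ratio <- function(light, dark, z1 = 0.05, z2 = 0.15) {
  sl <- local_gradient(light$depth_mm, light$O2_umol_L, z1, z2)
  sd_ <- local_gradient(dark$depth_mm, dark$O2_umol_L, z1, z2)
  if (abs(sd_) < sqrt(.Machine$double.eps)) return(NA_real_)
  abs(sl) / abs(sd_)
}

#' Brown-Forsythe (median-centered Levene) test of variance heterogeneity
#'
#' Robust Levene-type test on absolute deviations from group medians:
#' `Z_ij = |x_ij - median_i|`,
#' `W = ((N - k)/(k - 1)) * sum_i n_i (Zbar_i - Zbar)^2 / sum_ij (Z_ij - Zbar_i)^2`,
#' with p from `F(k - 1, N - k)`. Degenerate inputs (all deviations equal)
#' give `W = 0`, `p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `W`, `df1`, `df2`, `p_value`.
#' @export
brown_forsythe_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) >= 2L))
  k <- length(groups)
  Z <- lapply(groups, function(g) abs(g - stats::median(g)))
  n <- vapply(Z, length, integer(1))
  N <- sum(n)
  zbar_i <- vapply(Z, mean, numeric(1))
  zbar <- sum(unlist(Z)) / N
  num <- sum(n * (zbar_i - zbar)^2)
  den <- sum(vapply(seq_len(k), function(i) sum((Z[[i]] - zbar_i[i])^2),
                    numeric(1)))
  if (den <= .Machine$double.eps * N)
    return(list(W = 0, df1 = k - 1L, df2 = N - k, p_value = 1))
  W <- ((N - k) / (k - 1)) * num / den
  list(W = W, df1 = k - 1L, df2 = N - k,
       p_value = stats::pf(W, k - 1, N - k, lower.tail = FALSE))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, two-sided.
#' Thin wrapper over [stats::t.test()] returning a flat result; degenerate
#' equal constant samples give `t = 0`, `p = 1`.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2,
                  p_value = 1, mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Depth-binned (or wall-distance-binned) group comparison
#'
#' Pools readings of two profile sets into bins of `bin_mm` (default 0.1 mm,
#' i.e. 100 um steps) along depth or wall distance and runs a Welch test per
#' bin; p values are also Benjamini-Hochberg adjusted across bins. Bins with
#' fewer than 2 readings on either side are kept in the table but skipped
#' (`skipped = TRUE`, `note` says why).
#'
#' @param setA,setB [oxygen_profile_set()]s (or plain data frames with the
#'   same columns).
#' @param bin_mm bin width, mm.
#' @param grouping `"depth"` or `"wall_distance"`.
#' @param range_mm optional `c(lo, hi)` restriction on the binning variable.
#' @return data frame with `bin_lo_mm`, `bin_hi_mm`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t`, `p_value`, `q_value`, `skipped`, `note`.
#' @export
grouped_depth_compare <- function(setA, setB, bin_mm = 0.1,
                                  grouping = c("depth", "wall_distance"),
                                  range_mm = NULL) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "depth") "depth_mm" else "wall_distance_mm"
  va <- setA[[col]]; vb <- setB[[col]]
  if (!is.null(range_mm)) {
    selA <- va >= range_mm[1] & va <= range_mm[2]
    selB <- vb >= range_mm[1] & vb <= range_mm[2]
    setA <- setA[selA, , drop = FALSE]; setB <- setB[selB, , drop = FALSE]
    va <- va[selA]; vb <- vb[selB]
  }
  stopifnot(nrow(setA) > 0L, nrow(setB) > 0L)
  ba <- floor(va / bin_mm); bb <- floor(vb / bin_mm)
  bins <- sort(unique(c(ba, bb)))
  rows <- lapply(bins, function(b) {
    a <- setA$O2_umol_L[ba == b]; bvals <- setB$O2_umol_L[bb == b]
    out <- data.frame(bin_lo_mm = b * bin_mm, bin_hi_mm = (b + 1) * bin_mm,
                      n_a = length(a), n_b = length(bvals),
                      mean_a = NA_real_, mean_b = NA_real_, t = NA_real_,
                      p_value = NA_real_, skipped = TRUE, note = "")
    if (length(a) < 2L || length(bvals) < 2L) {
      out$note <- "fewer than 2 readings on one side; skipped"
      return(out)
    }
    w <- welch_test(a, bvals)
    out$mean_a <- w$mean_a; out$mean_b <- w$mean_b
    out$t <- w$t; out$p_value <- w$p_value; out$skipped <- FALSE
    out
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- NA_real_
  ok <- !tab$skipped
  tab$q_value[ok] <- stats::p.adjust(tab$p_value[ok], method = "BH")
  tab
}
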