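#' Segmented (broken-line) regression with a single breakpoint
#'
#' Fits `y = b0 + b1 * x + b2 * (x - psi)_+ + e`, estimating the breakpoint
#' `psi` by exhaustive grid search: candidate breakpoints are `n_grid`
#' x-quantiles between the `qrange` probabilities; at each candidate an
#' ordinary least-squares fit is computed and `psi` is the candidate
#' minimizing the residual sum of squares. Grid search is deterministic and
#' directly checkable against a brute-force split-point fit, unlike
#' iterative refitting schemes. Candidates with fewer than two distinct x
#' values on either side are dropped.
#'
#' For exactly linear data the segmented model offers no improvement and
#' `psi` is not identified; the fit is then flagged (`psi_identified =
#' FALSE`). A percentile bootstrap confidence interval for `psi` (resample
#' (x, y) pairs, refit) is computed when `n_boot_ci > 0`.
#'
#' @param x predictor (e.g., bed shear stress, Pa); at least 8 finite pairs.
#' @param y response (a landscape metric).
#' @param n_grid number of candidate quantiles (default 100).
#' @param qrange interior quantile range searched (default 5th-95th).
#' @param n_boot_ci bootstrap replicates for the `psi` CI (0 = skip).
#' @param conf CI level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return a `breakpoint_fit`: list with `psi`, `intercept`, `slope_below`,
#'   `slope_above`, `rss_segmented`, `rss_linear`, `psi_identified`,
#'   `psi_ci` (or `NULL`), `n`, and the model frame `x`, `y`.
#' @export
fit_segmented <- function(x, y, n_grid = 100L, qrange = c(0.05, 0.95),
                          n_boot_ci = 0L, conf = 0.95, seed = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 8L) stop("need at least 8 finite (x, y) pairs")
  if (length(unique(x)) < 4L) stop("x nearly constant; breakpoint not estimable")
  fit <- .seg_fit(x, y, n_grid, qrange)
  if (is.null(fit)) stop("no candidate breakpoint with enough points on both sides")
  lin <- stats::lm.fit(cbind(1, x), y)
  rss_lin <- sum(lin$residuals^2)
  identified <- (rss_lin - fit$rss) > 1e-10 * max(rss_lin, 1)
  psi_ci <- NULL
  if (n_boot_ci > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(x)
    boots <- vapply(seq_len(n_boot_ci), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(.seg_fit(x[i], y[i], n_grid, qrange),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$psi
    }, numeric(1))
    a <- (1 - conf) / 2
    psi_ci <- unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(psi = fit$psi, intercept = fit$beta[1],
                 slope_below = fit$beta[2],
                 slope_above = fit$beta[2] + fit$beta[3],
                 rss_segmented = fit$rss, rss_linear = rss_lin,
                 psi_identified = identified, psi_ci = psi_ci,
                 n = length(x), x = x, y = y),
            class = "breakpoint_fit")
}

# Candidate grid and pre-projected hinge columns for a fixed x.
# For each candidate psi, the segmented RSS is the linear RSS minus
# (r_z . r_y)^2 / (r_z . r_z), where r_z and r_y are the residuals of the
# hinge column (x - psi)_+ and of y after projecting out [1, x].
.seg_prep <- function(x, n_grid, qrange) {
  cand <- unique(stats::quantile(x, seq(qrange[1], qrange[2],
                                        length.out = n_grid), names = FALSE))
  ux <- sort(unique(x))
  cand <- cand[vapply(cand, function(p)
    sum(ux < p) >= 2L && sum(ux > p) >= 2L, logical(1))]
  if (length(cand) == 0L) return(NULL)
  qx <- qr(cbind(1, x))
  Z <- vapply(cand, function(p) pmax(x - p, 0), numeric(length(x)))
  Rz <- qr.resid(qx, Z)
  den <- colSums(Rz^2)
  keep <- den > 1e-12 * max(den, 1)
  if (!any(keep)) return(NULL)
  list(cand = cand[keep], qx = qx, Rz = Rz[, keep, drop = FALSE],
       den = den[keep])
}

# Grid-search OLS core; returns NULL if no admissible candidate.
.seg_fit <- function(x, y, n_grid, qrange, prep = NULL) {
  if (is.null(prep)) prep <- .seg_prep(x, n_grid, qrange)
  if (is.null(prep)) return(NULL)
  ry <- qr.resid(prep$qx, y)
  rss0 <- sum(ry^2)
  gain <- as.vector(crossprod(prep$Rz, ry))^2 / prep$den
  i <- which.max(gain)
  psi <- prep$cand[i]
  f <- stats::lm.fit(cbind(1, x, pmax(x - psi, 0)), y)
  list(psi = psi, beta = unname(f$coefficients), rss = max(rss0 - gain[i], 0))
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "breakpoint_fit: psi = %.4g%s, slopes %.4g -> %.4g, RSS %.4g (linear %.4g), n = %d\n",
    x$psi, if (x$psi_identified) "" else " (not identified)",
    x$slope_below, x$slope_above, x$rss_segmented, x$rss_linear, x$n))
  if (!is.null(x$psi_ci))
    cat(sprintf("  psi CI: [%.4g, %.4g]\n", x$psi_ci[1], x$psi_ci[2]))
  invisible(x)
}

#' Bootstrap significance of a breakpoint
#'
#' Parametric bootstrap under the no-breakpoint null: the linear model is
#' fitted, replicate responses are built as linear fitted values plus
#' resampled residuals, the segmented model is refitted to each replicate,
#' and the p value is the proportion of replicates whose F-type improvement
#' `F = ((rss_linear - rss_segmented) / 2) / (rss_segmented / (n - 4))`
#' reaches the observed one.
#'
#' @param fit a `breakpoint_fit` (carries its data).
#' @param n_boot bootstrap replicates (default 499; fewer than 100 triggers
#'   a warning).
#' @param seed RNG seed.
#' @param n_grid,qrange grid-search settings, as in [fit_segmented()].
#' @return list with `p_value`, `F_observed`, `n_boot`.
#' @export
breakpoint_significance <- function(fit, n_boot = 499L, seed = NULL,
                                    n_grid = 100L, qrange = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  if (n_boot < 100L) warning("n_boot < 100; p value will be coarse")
  if (!is.null(seed)) set.seed(seed)
  x <- fit$x; y <- fit$y; n <- fit$n
  Fstat <- function(rss_lin, rss_seg)
    ((rss_lin - rss_seg) / 2) / (rss_seg / (n - 4))
  F_obs <- Fstat(fit$rss_linear, fit$rss_segmented)
  lin <- stats::lm.fit(cbind(1, x), y)
  fitted0 <- y - lin$residuals
  res0 <- lin$residuals
  prep <- .seg_prep(x, n_grid, qrange)
  Yb <- fitted0 + matrix(sample(res0, n * n_boot, replace = TRUE), n, n_boot)
  Ry <- qr.resid(prep$qx, Yb)
  rss_lin_b <- colSums(Ry^2)
  gain <- crossprod(prep$Rz, Ry)^2 / prep$den        # candidates x replicates
  rss_seg_b <- pmax(rss_lin_b - apply(gain, 2L, max), 0)
  Fb <- Fstat(rss_lin_b, rss_seg_b)
  list(p_value = mean(Fb >= F_obs), F_observed = F_obs, n_boot = n_boot)
}

#' Consensus breakpoint range across replicate flumes
#'
#' If the breakpoint is significant (p < `alpha`) in every replicate, the
#' consensus is the range spanned by the replicate estimates; otherwise no
#' consensus is reported.
#'
#' @param fits list of `breakpoint_fit`s, one per replicate.
#' @param p_values numeric vector of matching p values.
#' @param alpha significance level (default 0.05).
#' @return `c(lo, hi)` in the units of x, or `NULL` when not significant in
#'   all replicates.
#' @export
replicate_consensus <- function(fits, p_values, alpha = 0.05) {
  stopifnot(length(fits) >= 2L, length(p_values) == length(fits))
  if (any(p_values >= alpha)) return(NULL)
  psis <- vapply(fits, function(f) f$psi, numeric(1))
  c(min(psis), max(psis))
}
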