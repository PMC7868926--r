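# Independent brute-force oracles used to check the package implementations.
# These deliberately use naive enumeration / textbook formulas, not the
# package's code paths.

# Haralick correlation by explicit pair enumeration over all pixels.
glcm_corr_brute <- function(h, n_levels, offsets) {
  mx <- max(h)
  q <- if (mx <= 0) matrix(1L, nrow(h), ncol(h)) else
    pmin(floor(h / mx * n_levels) + 1L, as.integer(n_levels))
  vals <- sapply(offsets, function(o) {
    dr <- o[1]; dc <- o[2]
    counts <- matrix(0, n_levels, n_levels)
    for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
        counts[q[i2, j2], q[i, j]] <- counts[q[i2, j2], q[i, j]] + 1
      }
    }
    p <- counts / sum(counts)
    lev <- seq_len(n_levels)
    mu <- sum(lev * rowSums(p))
    s2 <- sum((lev - mu)^2 * rowSums(p))
    if (s2 <= .Machine$double.eps) return(NA_real_)
    acc <- 0
    for (i in lev) for (j in lev) acc <- acc + (i - mu) * (j - mu) * p[i, j]
    acc / s2
  })
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# 8-connected labeling by breadth-first flood fill.
flood_fill_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- nxt
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# Brown-Forsythe W by explicit textbook formula with loops.
bf_oracle <- function(groups) {
  k <- length(groups)
  Z <- list(); N <- 0
  for (i in seq_len(k)) {
    Z[[i]] <- abs(groups[[i]] - median(groups[[i]]))
    N <- N + length(groups[[i]])
  }
  zbar <- mean(unlist(Z))
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    num <- num + length(Z[[i]]) * (mean(Z[[i]]) - zbar)^2
    for (zz in Z[[i]]) den <- den + (zz - mean(Z[[i]]))^2
  }
  ((N - k) / (k - 1)) * num / den
}

# Welch t and Satterthwaite df by explicit formula.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Brute-force segmented fit: try every midpoint between consecutive distinct
# x values (with >= 2 distinct x on each side) using lm().
seg_brute <- function(x, y) {
  ux <- sort(unique(x))
  cand <- (head(ux, -1) + tail(ux, -1)) / 2
  cand <- cand[sapply(cand, function(p) sum(ux < p) >= 2 && sum(ux > p) >= 2)]
  best <- NULL
  for (p in cand) {
    f <- lm(y ~ x + pmax(x - p, 0))
    rss <- sum(resid(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(psi = p, rss = rss)
  }
  best
}

# Small landscape parameter sets used across tests (kept tiny for speed).
tiny_sfm_params <- function(...) {
  landscape_params(extent_m = c(0.012, 0.03), tau_range = c(0.04, 0.05),
                   cluster_density_mm2 = 0, carpet_mean_mm = 0,
                   colony_density_mm2 = 0, noise_sd = 0, ...)
}

# A dem_grid wrapper for a plain matrix of heights (mm).
as_grid <- function(h, px = 0.04, day = 15L, ...) {
  dem_grid(h, pixel_size_xy = px, day = day, ...)
}
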