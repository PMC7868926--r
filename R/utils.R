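# Internal numerical helpers shared across modules.

# Summed-area table with a zero row/column prepended, so that
# sum over rows r1..r2, cols c1..c2 is S[r2+1,c2+1]-S[r1,c2+1]-S[r2+1,c1]+S[r1,c1].
.sat <- function(m) {
  s <- apply(m, 2L, cumsum)
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(m))
  s <- t(apply(s, 1L, cumsum))
  if (is.null(dim(s))) s <- matrix(s, ncol = ncol(m))
  rbind(0, cbind(0, s))
}

# Moving box mean over a (2k+1)-square window, truncated at the grid edge:
# each pixel's mean is taken over the window pixels that fall inside the grid.
.box_mean <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  S <- .sat(m)
  C <- .sat(matrix(1, nr, nc))
  r1 <- pmax(seq_len(nr) - k, 1L); r2 <- pmin(seq_len(nr) + k, nr)
  c1 <- pmax(seq_len(nc) - k, 1L); c2 <- pmin(seq_len(nc) + k, nc)
  R1 <- matrix(r1, nr, nc); R2 <- matrix(r2, nr, nc)
  C1 <- matrix(c1, nr, nc, byrow = TRUE); C2 <- matrix(c2, nr, nc, byrow = TRUE)
  idx <- function(S, i, j) S[cbind(as.vector(i) + 1L, as.vector(j) + 1L)]
  tot <- idx(S, R2, C2) - idx(S, R1 - 1L, C2) - idx(S, R2, C1 - 1L) + idx(S, R1 - 1L, C1 - 1L)
  cnt <- idx(C, R2, C2) - idx(C, R1 - 1L, C2) - idx(C, R2, C1 - 1L) + idx(C, R1 - 1L, C1 - 1L)
  matrix(tot / cnt, nr, nc)
}

# Resolve a region spec (NULL = whole grid, or c(r1, r2, c1, c2), 1-based
# inclusive) against a height matrix; errors on empty/out-of-range regions.
.region <- function(heights, region) {
  if (is.null(region)) return(c(1L, nrow(heights), 1L, ncol(heights)))
  region <- as.integer(region)
  if (length(region) != 4L) stop("region must be c(r1, r2, c1, c2)")
  if (region[1] < 1L || region[3] < 1L || region[2] > nrow(heights) ||
      region[4] > ncol(heights) || region[1] > region[2] || region[3] > region[4])
    stop("empty or out-of-range region")
  region
}

.submat <- function(heights, region) {
  r <- .region(heights, region)
  heights[r[1]:r[2], r[3]:r[4], drop = FALSE]
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
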