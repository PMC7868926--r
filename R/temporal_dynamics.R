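#' Difference of two consecutive DEMs
#'
#' Computes the per-pixel height change `delta = later - earlier` (mm) and
#' the biovolume it represents: `positive_volume` (local accumulation) and
#' `negative_volume` (local loss, reported as a positive magnitude, the
#' "negative growth" signature of detachment or downstream displacement).
#' The conservation identity
#' `positive_volume - negative_volume == biovolume(g2) - biovolume(g1)`
#' holds exactly when `min_delta = 0` (the default). Setting `min_delta`
#' to, e.g., one height quantum zeroes small `|delta|` before the volume
#' sums to suppress quantization flicker, at the cost of that identity.
#'
#' `displaced_fraction` is `negative_volume` divided by the total biovolume
#' at the later day (`denominator = "later"`, default), the earlier day, or
#' their mean.
#'
#' @param g1,g2 [dem_grid()]s with identical geometry, `g2$day > g1$day`.
#' @param min_delta magnitude below which deltas are zeroed before summing
#'   (mm, default 0).
#' @param denominator denominator convention for `displaced_fraction`.
#' @return a `diff_map`: list with `delta` (matrix, mm), `day_pair`,
#'   `positive_volume`, `negative_volume` (mm^3), `displaced_fraction`.
#' @export
dem_difference <- function(g1, g2, min_delta = 0,
                           denominator = c("later", "earlier", "mean")) {
  denominator <- match.arg(denominator)
  if (!identical(dim(g1$heights), dim(g2$heights)) ||
      !isTRUE(all.equal(g1$pixel_size_xy, g2$pixel_size_xy)))
    stop("DEM geometry mismatch")
  if (g2$day <= g1$day) stop("g2 must be acquired after g1")
  delta <- g2$heights - g1$heights
  d <- delta
  if (min_delta > 0) d[abs(d) <= min_delta * (1 + 1e-9)] <- 0
  px2 <- g1$pixel_size_xy^2
  pos <- sum(pmax(d, 0)) * px2
  neg <- sum(pmax(-d, 0)) * px2
  denomV <- switch(denominator,
                   later = biovolume(g2), earlier = biovolume(g1),
                   mean = (biovolume(g1) + biovolume(g2)) / 2)
  structure(list(delta = delta, day_pair = c(g1$day, g2$day),
                 positive_volume = pos, negative_volume = neg,
                 displaced_fraction = if (denomV > 0) neg / denomV else 0),
            class = "diff_map")
}

#' @export
print.diff_map <- function(x, ...) {
  cat(sprintf(
    "diff_map day %d -> %d: +%.4g mm3, -%.4g mm3, displaced fraction %.3g\n",
    x$day_pair[1], x$day_pair[2], x$positive_volume, x$negative_volume,
    x$displaced_fraction))
  invisible(x)
}

#' Biovolume accrual rates over a DEM series
#'
#' For each consecutive day pair, `(V(t2) - V(t1)) / (t2 - t1)` in mm^3/day
#' over the given region; rates may be negative (net loss).
#'
#' @param series a [dem_series()] with at least two grids.
#' @param region region passed to [biovolume()].
#' @return data frame with `day_from`, `day_to`, `volume_from_mm3`,
#'   `volume_to_mm3`, `accrual_mm3_day`.
#' @export
accrual_rate <- function(series, region = NULL) {
  stopifnot(inherits(series, "dem_series"), length(series) >= 2L)
  g <- series$grids
  days <- vapply(g, function(x) x$day, integer(1))
  vols <- vapply(g, biovolume, numeric(1), region = region)
  n <- length(g)
  data.frame(day_from = days[-n], day_to = days[-1],
             volume_from_mm3 = vols[-n], volume_to_mm3 = vols[-1],
             accrual_mm3_day = diff(vols) / diff(days))
}

#' Summarize displacement over a DEM series
#'
#' Applies [dem_difference()] to every consecutive pair.
#'
#' @inheritParams accrual_rate
#' @param ... passed to [dem_difference()].
#' @return data frame with one row per day pair: `day_from`, `day_to`,
#'   `positive_volume_mm3`, `negative_volume_mm3`, `displaced_fraction`.
#' @export
series_displacement <- function(series, ...) {
  stopifnot(inherits(series, "dem_series"), length(series) >= 2L)
  g <- series$grids
  rows <- lapply(seq_len(length(g) - 1L), function(i) {
    dm <- dem_difference(g[[i]], g[[i + 1L]], ...)
    data.frame(day_from = dm$day_pair[1], day_to = dm$day_pair[2],
               positive_volume_mm3 = dm$positive_volume,
               negative_volume_mm3 = dm$negative_volume,
               displaced_fraction = dm$displaced_fraction)
  })
  do.call(rbind, rows)
}
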