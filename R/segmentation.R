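#' Segment a biofilm landscape by deviation from local average thickness
#'
#' Classifies every pixel relative to the moving-average thickness of its
#' local neighborhood (a square window of `local_window_mm` edge, zeros
#' included, truncated at grid edges):
#' \itemize{
#'   \item `bare`: thickness below the detection threshold `h_min`;
#'   \item `cluster`: thickness at least `k_hi` times the local average
#'     (protruding structures);
#'   \item `trough`: thickness at most `1/k_lo` of the local average
#'     (depressions between clusters);
#'   \item `base`: everything else (the base biofilm).
#' }
#' Thresholds are relative, so the classification is invariant to a global
#' height rescaling when `h_min` is rescaled likewise. Uncolonized substrate
#' (`bare`) is kept separate from `trough` so trough fractions are not
#' inflated by bare plexiglass; the merged trough+bare fraction is also
#' reported.
#'
#' @param grid a [dem_grid()].
#' @param local_window_mm local averaging window edge, mm (default 24, the
#'   same scale as the moving-window metrics).
#' @param k_hi cluster threshold multiplier (> 1, default 2).
#' @param k_lo trough threshold divisor (> 1, default 2).
#' @param h_min detection threshold, mm.
#' @param covered_only if `TRUE`, the local mean is computed over covered
#'   pixels only (default `FALSE`: landscape average, zeros included).
#' @return a `segmentation_map`: list with `labels` (integer matrix, 0 =
#'   bare, 1 = trough, 2 = base, 3 = cluster), `local_mean` (matrix, mm),
#'   `fractions` (named vector `f_bare`, `f_trough`, `f_base`, `f_cluster`,
#'   summing to 1, plus `f_trough_merged = f_trough + f_bare`), and
#'   `parameters`.
#' @export
segment_landscape <- function(grid, local_window_mm = 24, k_hi = 2,
                              k_lo = 2, h_min = 0.010,
                              covered_only = FALSE) {
  stopifnot(k_hi > 1, k_lo > 1)
  px <- grid$pixel_size_xy
  h <- grid$heights
  win_px <- round(local_window_mm / px)
  if (win_px < 10L) stop("local window must span at least 10 pixels")
  if (win_px > max(dim(h))) stop("local window exceeds grid extent")
  k <- win_px %/% 2L
  if (covered_only) {
    cov <- (h >= h_min) * 1
    num <- .box_mean(h * cov, k)
    den <- .box_mean(cov, k)
    lm_ <- ifelse(den > 0, num / den, 0)
  } else {
    lm_ <- .box_mean(h, k)
  }
  labels <- matrix(2L, nrow(h), ncol(h))           # base
  labels[h >= k_hi * lm_] <- 3L                    # cluster
  labels[h <= lm_ / k_lo] <- 1L                    # trough
  labels[h < h_min] <- 0L                          # bare wins
  n <- length(labels)
  fr <- c(f_bare = sum(labels == 0L) / n, f_trough = sum(labels == 1L) / n,
          f_base = sum(labels == 2L) / n, f_cluster = sum(labels == 3L) / n)
  fr <- c(fr, f_trough_merged = unname(fr["f_trough"] + fr["f_bare"]))
  structure(list(labels = labels, local_mean = lm_, fractions = fr,
                 parameters = list(local_window_mm = local_window_mm,
                                   k_hi = k_hi, k_lo = k_lo, h_min = h_min,
                                   covered_only = covered_only)),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat("segmentation_map:", paste(sprintf("%s=%.3f", names(x$fractions),
                                         x$fractions), collapse = " "), "\n")
  invisible(x)
}

# 8-connected labeling of a binary mask. EBImage::bwlabel is 4-connected, so
# labels that touch only diagonally are merged afterwards with union-find.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  pairs <- NULL
  nr <- nrow(lab); nc <- ncol(lab)
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    c1 <- max(1L, 1L - d[2]); c2 <- min(nc, nc - d[2])
    a <- lab[1:(nr - 1L), c1:c2, drop = FALSE]
    b <- lab[2:nr, (c1 + d[2]):(c2 + d[2]), drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Extract per-cluster morphology from a segmentation
#'
#' Connected components (8-connectivity) of cluster-labeled pixels;
#' components smaller than `min_area_mm2` are discarded as speckle. For each
#' retained cluster: area, volume, max height, equivalent diameter
#' (`2 * sqrt(area / pi)`), bounding extents along the flow (x) and across
#' it (y), vertical aspect (`max_height / equivalent_diameter`), horizontal
#' aspect (`length_flow / width_cross`), and centroid.
#'
#' @param segmap a `segmentation_map` from [segment_landscape()].
#' @param grid the [dem_grid()] the map was computed from.
#' @param min_area_mm2 minimum cluster footprint, mm^2 (default 0.01,
#'   below the <0.1 mm colony scale; suppresses single-pixel speckle).
#' @return list with `clusters` (data frame of per-cluster statistics,
#'   possibly 0 rows), `abundance` (retained cluster count) and
#'   `cumulative` (data frame: sorted `volume_mm3`, `n_ge` = number of
#'   clusters at least that large — the cumulative size histogram).
#' @export
extract_clusters <- function(segmap, grid, min_area_mm2 = 0.01) {
  stopifnot(inherits(segmap, "segmentation_map"),
            identical(dim(segmap$labels), dim(grid$heights)))
  px <- grid$pixel_size_xy
  lab <- .label8(segmap$labels == 3L)
  nlab <- max(lab)
  empty <- data.frame(id = integer(), area_mm2 = numeric(),
                      volume_mm3 = numeric(), max_height_mm = numeric(),
                      equivalent_diameter_mm = numeric(),
                      length_flow_mm = numeric(), width_cross_mm = numeric(),
                      vertical_aspect = numeric(), horizontal_aspect = numeric(),
                      centroid_x_m = numeric(), centroid_y_mm = numeric())
  if (nlab == 0L)
    return(list(clusters = empty, abundance = 0L,
                cumulative = data.frame(volume_mm3 = numeric(), n_ge = integer())))
  idx <- which(lab > 0L)
  li <- lab[idx]
  hi <- grid$heights[idx]
  ri <- (idx - 1L) %% nrow(lab) + 1L
  ci <- (idx - 1L) %/% nrow(lab) + 1L
  npix <- tabulate(li, nlab)
  vol <- as.vector(tapply(hi, li, sum)) * px^2
  mx  <- as.vector(tapply(hi, li, max))
  rmin <- as.vector(tapply(ri, li, min)); rmax <- as.vector(tapply(ri, li, max))
  cmin <- as.vector(tapply(ci, li, min)); cmax <- as.vector(tapply(ci, li, max))
  rbar <- as.vector(tapply(ri, li, mean)); cbar <- as.vector(tapply(ci, li, mean))
  area <- npix * px^2
  eqd <- 2 * sqrt(area / pi)
  lenx <- (cmax - cmin + 1L) * px
  wid <- (rmax - rmin + 1L) * px
  cl <- data.frame(
    id = seq_len(nlab), area_mm2 = area, volume_mm3 = vol,
    max_height_mm = mx, equivalent_diameter_mm = eqd,
    length_flow_mm = lenx, width_cross_mm = wid,
    vertical_aspect = mx / eqd, horizontal_aspect = lenx / wid,
    centroid_x_m = grid$x_origin + (cbar - 0.5) * px / 1000,
    centroid_y_mm = (rbar - 0.5) * px)
  cl <- cl[cl$area_mm2 >= min_area_mm2, , drop = FALSE]
  cl$id <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  v <- sort(cl$volume_mm3)
  list(clusters = cl, abundance = nrow(cl),
       cumulative = data.frame(volume_mm3 = v,
                               n_ge = rev(seq_along(v))))
}

#' Write a segmentation label raster as 8-bit TIFF
#'
#' Gray levels: 0 = bare, 1 = trough, 2 = base, 3 = cluster.
#'
#' @param segmap a `segmentation_map`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(segmap, path) {
  tiff::writeTIFF(segmap$labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}
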