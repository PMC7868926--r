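#' DEM grid of biofilm surface topography
#'
#' A `dem_grid` holds one digital elevation model (DEM) of the biofilm
#' surface: a matrix of biofilm thickness values in mm, with rows running
#' across the flume (y) and columns running streamwise (x, flow direction).
#' Pixel centers sit at `(i - 0.5) * pixel_size_xy` from the grid edge;
#' column 1 starts at the streamwise origin `x_origin` (m).
#'
#' OCT-derived DEMs are quantized in height (one gray level = `z_quantum` mm)
#' and cannot resolve structures taller than the instrument ceiling
#' (`clip_height`, ~1.2 mm); pixels at or above the ceiling are flagged in a
#' companion clipping mask and reported by [clipping_fraction()].
#'
#' @param heights numeric matrix of thickness values (mm, all >= 0).
#' @param pixel_size_xy lateral pixel size in mm (default 0.040).
#' @param z_quantum height quantization step in mm (default 0.00218).
#' @param x_origin streamwise position of the first column, m.
#' @param day acquisition day (integer >= 0).
#' @param flume_id replicate identifier.
#' @param clip_height instrument depth ceiling in mm used to flag clipped
#'   pixels (default 1.2).
#' @return an object of class `dem_grid`.
#' @export
dem_grid <- function(heights, pixel_size_xy = 0.040, z_quantum = 0.00218,
                     x_origin = 0, day = 0L, flume_id = "I",
                     clip_height = 1.2) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  g <- structure(
    list(heights = heights, pixel_size_xy = pixel_size_xy,
         z_quantum = z_quantum, x_origin = x_origin, day = as.integer(day),
         flume_id = as.character(flume_id), clip_height = clip_height),
    class = "dem_grid")
  validate_dem_grid(g)
  g
}

#' Validate a DEM grid
#'
#' Checks the `dem_grid` invariants: non-empty matrix, positive pixel size,
#' non-negative heights, non-negative integer day.
#'
#' @param g a `dem_grid`.
#' @return `g`, invisibly; errors naming the first offending cell otherwise.
#' @export
validate_dem_grid <- function(g) {
  stopifnot(inherits(g, "dem_grid"))
  if (!is.matrix(g$heights) || length(g$heights) == 0L)
    stop("heights must be a non-empty matrix")
  if (!is.numeric(g$pixel_size_xy) || g$pixel_size_xy <= 0)
    stop("pixel_size_xy must be > 0")
  if (!is.numeric(g$z_quantum) || g$z_quantum <= 0)
    stop("z_quantum must be > 0")
  bad <- which(!is.finite(g$heights) | g$heights < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid height %.6g at cell (row %d, col %d)",
                 g$heights[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  if (is.na(g$day) || g$day < 0L) stop("day must be a non-negative integer")
  invisible(g)
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf(
    "dem_grid: %d x %d px (%.3g x %.3g mm), day %d, flume %s\n",
    nrow(x$heights), ncol(x$heights),
    nrow(x$heights) * x$pixel_size_xy, ncol(x$heights) * x$pixel_size_xy,
    x$day, x$flume_id))
  cat(sprintf("  pixel %.3g mm, z quantum %.4g mm, x origin %.4g m\n",
              x$pixel_size_xy, x$z_quantum, x$x_origin))
  cat(sprintf("  heights: max %.3g mm, mean %.3g mm, clipped %.2g%%\n",
              max(x$heights), mean(x$heights), 100 * clipping_fraction(x)))
  invisible(x)
}

#' Streamwise coordinates of grid columns
#'
#' @param g a `dem_grid`.
#' @return numeric vector of column-center positions in m.
#' @export
dem_x_coords <- function(g) {
  g$x_origin + (seq_len(ncol(g$heights)) - 0.5) * g$pixel_size_xy / 1000
}

#' Mask and fraction of depth-clipped pixels
#'
#' Pixels at or above the instrument depth ceiling are not reliably imaged;
#' they are kept as valid heights but flagged here as a diagnostic.
#'
#' @param g a `dem_grid`.
#' @return `clipping_mask()`: logical matrix; `clipping_fraction()`: scalar
#'   fraction of flagged pixels.
#' @export
clipping_mask <- function(g) {
  g$heights >= g$clip_height - g$z_quantum / 2
}

#' @rdname clipping_mask
#' @export
clipping_fraction <- function(g) mean(clipping_mask(g))

#' Time-ordered series of DEM grids
#'
#' Bundles DEMs of the same flume region acquired on different days.
#' Grids must share geometry (shape, pixel size, streamwise origin) and have
#' strictly increasing acquisition days; grids are sorted by day. Automated
#' OCT re-scans fixed positions, so the series is declared `assumed-aligned`
#' by default; no registration is applied (registration would erase the
#' displacement signal that the temporal analysis measures).
#'
#' @param grids list of `dem_grid` objects.
#' @param alignment spatial registration status string.
#' @return an object of class `dem_series`.
#' @export
dem_series <- function(grids, alignment = "assumed-aligned") {
  stopifnot(is.list(grids), length(grids) >= 1L)
  lapply(grids, validate_dem_grid)
  days <- vapply(grids, function(g) g$day, integer(1))
  if (anyDuplicated(days)) stop("duplicate acquisition days: ",
                                paste(days[duplicated(days)], collapse = ", "))
  grids <- grids[order(days)]
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    gi <- grids[[i]]
    if (!identical(dim(gi$heights), dim(ref$heights)))
      stop(sprintf("grid shape mismatch between day %d (%dx%d) and day %d (%dx%d)",
                   ref$day, nrow(ref$heights), ncol(ref$heights),
                   gi$day, nrow(gi$heights), ncol(gi$heights)))
    if (!isTRUE(all.equal(gi$pixel_size_xy, ref$pixel_size_xy)) ||
        !isTRUE(all.equal(gi$x_origin, ref$x_origin)))
      stop(sprintf("geometry metadata mismatch between day %d and day %d",
                   ref$day, gi$day))
  }
  structure(list(grids = grids, alignment = alignment), class = "dem_series")
}

#' @export
print.dem_series <- function(x, ...) {
  days <- vapply(x$grids, function(g) g$day, integer(1))
  cat(sprintf("dem_series: %d grids, days %s, alignment %s\n",
              length(x$grids), paste(days, collapse = ", "), x$alignment))
  invisible(x)
}

#' @export
length.dem_series <- function(x) length(x$grids)
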