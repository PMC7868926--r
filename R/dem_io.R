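#' Read a biofilm DEM from TIFF or a delimited text grid
#'
#' For 16-bit grayscale TIFF, biofilm thickness is encoded as the pixel gray
#' level in height-quantum units: `height_mm = gray_level * z_quantum`.
#' Plain-text grids (whitespace- or comma-delimited) are read as thickness in
#' mm directly. Metadata (pixel size, height quantum, streamwise origin, day,
#' flume id) is taken from a YAML sidecar `<path>.yaml` when present; values
#' passed in `meta` override the sidecar. Sidecar keys: `pixel_size_um`,
#' `z_quantum_um`, `x_origin_m`, `day`, `flume_id`, `clip_height_um`.
#'
#' @param path path to a `.tif`/`.tiff` file or a text grid.
#' @param meta named list of metadata overrides, using [dem_grid()] argument
#'   names (`pixel_size_xy` and `z_quantum` in mm).
#' @return a [dem_grid()].
#' @export
read_dem <- function(path, meta = list()) {
  if (!file.exists(path) || dir.exists(path)) stop("cannot read DEM file: ", path)
  side <- .read_sidecar(paste0(path, ".yaml"))
  args <- utils::modifyList(side, meta)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    gray <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(gray)) == 3L) gray <- gray[, , 1]
    zq <- if (!is.null(args$z_quantum)) args$z_quantum else 0.00218
    heights <- gray * zq
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    heights <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                           comment.char = "#"))
    dimnames(heights) <- NULL
    bad <- which(heights < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("negative height %.6g at cell (row %d, col %d) in %s",
                   heights[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path))
  }
  do.call(dem_grid, c(list(heights = heights), args))
}

#' Write a biofilm DEM as 16-bit grayscale TIFF plus YAML sidecar
#'
#' Heights are encoded as `round(height / z_quantum)` gray levels, so the
#' round trip `read_dem(write_dem(g))` reproduces heights to within half a
#' height quantum (bit-identically for already-quantized grids) and metadata
#' exactly via the sidecar. Gray levels above 65535 (heights beyond
#' `65535 * z_quantum` mm) are saturated with a warning.
#'
#' @param grid a [dem_grid()].
#' @param path output path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_dem <- function(grid, path) {
  validate_dem_grid(grid)
  if (dir.exists(path)) stop("cannot write DEM to a directory: ", path)
  gray <- round(grid$heights / grid$z_quantum)
  if (any(gray > 65535)) {
    warning("heights exceed 16-bit range; saturating at 65535 gray levels")
    gray <- pmin(gray, 65535)
  }
  ok <- tryCatch(tiff::writeTIFF(gray / 65535, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write DEM file: ", path,
                                          " (", conditionMessage(e), ")"))
  .write_sidecar(grid, paste0(path, ".yaml"))
  invisible(path)
}

.write_sidecar <- function(grid, path) {
  yaml::write_yaml(list(
    pixel_size_um = grid$pixel_size_xy * 1000,
    z_quantum_um  = grid$z_quantum * 1000,
    x_origin_m    = grid$x_origin,
    day           = grid$day,
    flume_id      = grid$flume_id,
    clip_height_um = grid$clip_height * 1000), path)
}

.read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$pixel_size_um)) out$pixel_size_xy <- y$pixel_size_um / 1000
  if (!is.null(y$z_quantum_um))  out$z_quantum <- y$z_quantum_um / 1000
  if (!is.null(y$x_origin_m))    out$x_origin <- y$x_origin_m
  if (!is.null(y$day))           out$day <- as.integer(y$day)
  if (!is.null(y$flume_id))      out$flume_id <- y$flume_id
  if (!is.null(y$clip_height_um)) out$clip_height <- y$clip_height_um / 1000
  out
}

#' Load a time series of DEMs from a manifest
#'
#' The manifest is a data frame or CSV file with columns `path`, `day`, and
#' optionally `flume_id` and `x_origin_m`. Grids are read with [read_dem()],
#' sorted by day, and checked for consistent geometry.
#'
#' @param manifest data frame or path to a manifest CSV.
#' @param meta metadata overrides applied to every entry (see [read_dem()]).
#' @return a [dem_series()].
#' @export
load_series <- function(manifest, meta = list()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L,
            all(c("path", "day") %in% names(manifest)))
  grids <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- meta
    m$day <- as.integer(manifest$day[i])
    if (!is.null(manifest$flume_id)) m$flume_id <- manifest$flume_id[i]
    if (!is.null(manifest$x_origin_m)) m$x_origin <- manifest$x_origin_m[i]
    read_dem(manifest$path[i], meta = m)
  })
  dem_series(grids)
}
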