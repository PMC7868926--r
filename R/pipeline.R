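#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' every stage enabled and module parameters at their defaults. Any element
#' can be overridden by the `config` argument of [run_pipeline()] (or by a
#' YAML file with the same structure).
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "metrics", "segment", "dynamics", "breakpoint",
               "oxygen"),
    simulate = list(landscape = list(), days = c(0, 3, 6, 9, 12, 15),
                    doubling_days = 3, detach_prob = 0.05,
                    displace_prob = 0.10, shift_px = 10L,
                    oxygen = list()),
    inputs = list(manifest = NULL, hydraulic_profile = NULL,
                  oxygen_files = NULL),
    metrics = list(window_mm = 24, step_mm = 2, h_min = 0.010,
                   n_levels = 64L),
    segment = list(local_window_mm = 24, k_hi = 2, k_lo = 2, h_min = 0.010,
                   min_area_mm2 = 0.01),
    dynamics = list(min_delta = 0, denominator = "later"),
    breakpoint = list(metrics = c("volume_mm3", "coverage", "porosity",
                                  "mean_thickness_mm"),
                      n_boot = 499L, thin_mm = 24, alpha = 0.05),
    oxygen = list(bin_mm = 0.1, z1 = 0.05, z2 = 0.15))
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

.pipe_log <- function(con, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", msg)
  writeLines(line, con)
  message(line)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order — `simulate` (synthetic DEM series,
#' hydraulic profile and oxygen profiles, with ground truth), `metrics`
#' (moving-window landscape metrics), `segment` (landscape classification
#' and cluster morphology), `dynamics` (DEM differencing and accrual),
#' `breakpoint` (segmented regression of metrics against shear), and
#' `oxygen` (microprofile statistics) — writing every stage's tables under
#' `out_dir` together with a timestamped log recording the seed and
#' configuration. Re-running with the same configuration and seed
#' reproduces the deterministic outputs bit-identically.
#'
#' Without a `simulate` stage, the `inputs` section must point at a DEM
#' manifest CSV, a hydraulic profile CSV and (for the oxygen stage) profile
#' CSVs readable by [load_series()], [hydraulic_profile()] and
#' [parse_profiles()].
#'
#' @param config partial configuration list or path to a YAML file;
#'   defaults from [default_pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the key in-memory results per stage.
#' @export
run_pipeline <- function(config = list(), out_dir = "pipeline_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  .pipe_log(con, sprintf("pipeline start; seed=%d; stages=%s", cfg$seed,
                         paste(cfg$stages, collapse = ",")))
  yaml::write_yaml(cfg, file.path(out_dir, "config_used.yaml"))
  res <- list(config = cfg)

  if ("simulate" %in% cfg$stages) {
    .pipe_log(con, "stage simulate")
    lp <- do.call(landscape_params, cfg$simulate$landscape)
    ts <- gen_timeseries(lp, days = cfg$simulate$days,
                         doubling_days = cfg$simulate$doubling_days,
                         detach_prob = cfg$simulate$detach_prob,
                         displace_prob = cfg$simulate$displace_prob,
                         shift_px = cfg$simulate$shift_px, seed = cfg$seed)
    res$series <- ts$series; res$truth <- ts$truth
    dem_dir <- file.path(out_dir, "dems")
    dir.create(dem_dir, showWarnings = FALSE)
    manifest <- do.call(rbind, lapply(ts$series$grids, function(g) {
      p <- file.path(dem_dir, sprintf("day%02d.tif", g$day))
      write_dem(g, p)
      data.frame(path = p, day = g$day, flume_id = g$flume_id,
                 x_origin_m = g$x_origin)
    }))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    res$profile <- gen_hydraulic_profile(
      x_range = c(0, lp$extent_m[2]), tau_range = lp$tau_range)
    utils::write.csv(res$profile, file.path(out_dir, "hydraulic_profile.csv"),
                     row.names = FALSE)
    ox <- do.call(oxygen_params, cfg$simulate$oxygen)
    res$oxygen <- gen_oxygen(ox, seed = cfg$seed)
    utils::write.csv(res$oxygen$profiles,
                     file.path(out_dir, "oxygen_profiles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(event_log = ts$truth$event_log, clusters = ts$truth$clusters,
           seed = cfg$seed),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    .pipe_log(con, "stage simulate skipped; loading inputs")
    if (!is.null(cfg$inputs$manifest)) res$series <- load_series(cfg$inputs$manifest)
    if (!is.null(cfg$inputs$hydraulic_profile))
      res$profile <- hydraulic_profile(cfg$inputs$hydraulic_profile)
    if (!is.null(cfg$inputs$oxygen_files))
      res$oxygen <- list(profiles = parse_profiles(cfg$inputs$oxygen_files))
  }

  final <- function() res$series$grids[[length(res$series)]]
  previous <- function() res$series$grids[[length(res$series) - 1L]]

  if ("metrics" %in% cfg$stages) {
    .pipe_log(con, "stage metrics")
    m <- cfg$metrics
    res$window_metrics <- moving_window_metrics(
      final(), res$profile, window_mm = m$window_mm, step_mm = m$step_mm,
      h_min = m$h_min, prev = if (length(res$series) > 1L) previous(),
      n_levels = m$n_levels)
    utils::write.csv(res$window_metrics,
                     file.path(out_dir, "window_metrics.csv"),
                     row.names = FALSE)
  }

  if ("segment" %in% cfg$stages) {
    .pipe_log(con, "stage segment")
    s <- cfg$segment
    segmap <- segment_landscape(final(), local_window_mm = s$local_window_mm,
                                k_hi = s$k_hi, k_lo = s$k_lo, h_min = s$h_min)
    res$segmentation <- segmap
    res$clusters <- extract_clusters(segmap, final(),
                                     min_area_mm2 = s$min_area_mm2)
    write_labels(segmap, file.path(out_dir, "labels.tif"))
    utils::write.csv(res$clusters$clusters,
                     file.path(out_dir, "cluster_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(t(segmap$fractions)),
                     file.path(out_dir, "class_fractions.csv"),
                     row.names = FALSE)
  }

  if ("dynamics" %in% cfg$stages && length(res$series) > 1L) {
    .pipe_log(con, "stage dynamics")
    d <- cfg$dynamics
    res$displacement <- series_displacement(res$series,
                                            min_delta = d$min_delta,
                                            denominator = d$denominator)
    res$accrual <- accrual_rate(res$series)
    utils::write.csv(res$displacement, file.path(out_dir, "displacement.csv"),
                     row.names = FALSE)
    utils::write.csv(res$accrual, file.path(out_dir, "accrual.csv"),
                     row.names = FALSE)
  }

  if ("breakpoint" %in% cfg$stages && !is.null(res$window_metrics)) {
    .pipe_log(con, "stage breakpoint")
    b <- cfg$breakpoint
    wm <- res$window_metrics
    # thin to non-overlapping windows for inference
    keep <- !duplicated(floor((wm$center_x_m - wm$center_x_m[1]) /
                                (b$thin_mm / 1000)))
    fits <- lapply(b$metrics, function(mn) {
      y <- wm[[mn]]
      f <- tryCatch(fit_segmented(wm$tau_Pa, y), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      ft <- tryCatch(fit_segmented(wm$tau_Pa[keep], y[keep]),
                     error = function(e) f)
      sig <- breakpoint_significance(ft, n_boot = b$n_boot,
                                     seed = cfg$seed + 1L)
      list(metric = mn, psi_Pa = f$psi, slope_below = f$slope_below,
           slope_above = f$slope_above, p_value = sig$p_value,
           psi_identified = f$psi_identified)
    })
    fits <- Filter(Negate(is.null), fits)
    res$breakpoints <- fits
    jsonlite::write_json(fits, file.path(out_dir, "breakpoint_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("oxygen" %in% cfg$stages && !is.null(res$oxygen)) {
    .pipe_log(con, "stage oxygen")
    o <- cfg$oxygen
    res$oxygen_stats <- oxygen_profile_stats(res$oxygen$profiles,
                                             z1 = o$z1, z2 = o$z2,
                                             bin_mm = o$bin_mm)
    utils::write.csv(res$oxygen_stats$depth_compare,
                     file.path(out_dir, "oxygen_depth_compare.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$oxygen_stats[c("brown_forsythe_dark",
                                            "brown_forsythe_light",
                                            "light_dark_welch")],
                         file.path(out_dir, "oxygen_tests.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  .pipe_log(con, "pipeline done")
  invisible(res)
}

#' Standard statistics over an oxygen profile set
#'
#' Convenience summary used by the pipeline: Brown-Forsythe variance
#' heterogeneity of within-biofilm concentrations between morphotypes
#' (dark and light separately), per-location light:dark gradient ratios
#' with a Welch comparison between morphotypes, a depth-binned comparison
#' of morphotypes (dark), and a wall-vs-core depth-binned comparison within
#' the slow-flow morphotype when wall distances are tagged.
#'
#' @param profiles an [oxygen_profile_set()].
#' @param z1,z2 gradient depth window, mm.
#' @param bin_mm depth bin width, mm.
#' @return list with `brown_forsythe_dark`, `brown_forsythe_light`,
#'   `ratios` (per-location data frame), `light_dark_welch`,
#'   `depth_compare`, and `wall_compare` (or `NULL`).
#' @export
oxygen_profile_stats <- function(profiles, z1 = 0.05, z2 = 0.15,
                                 bin_mm = 0.1) {
  stopifnot(inherits(profiles, "oxygen_profile_set"))
  inb <- profiles[profiles$depth_mm >= 0, ]
  grp <- function(cond) list(
    SFM = inb$O2_umol_L[inb$morphotype == "SFM" & inb$condition == cond],
    FFM = inb$O2_umol_L[inb$morphotype == "FFM" & inb$condition == cond])
  bf_dark <- brown_forsythe_test(grp("dark"))
  bf_light <- brown_forsythe_test(grp("light"))

  ids <- unique(profiles$profile_id[is.na(profiles$wall_distance_mm)])
  ratios <- do.call(rbind, lapply(ids, function(id) {
    p <- profiles[profiles$profile_id == id, ]
    li <- p[p$condition == "light", ]; dk <- p[p$condition == "dark", ]
    if (nrow(li) == 0L || nrow(dk) == 0L) return(NULL)
    data.frame(profile_id = id, morphotype = p$morphotype[1],
               ratio = light_dark_ratio(li, dk, z1, z2))
  }))
  ldw <- if (!is.null(ratios) && length(unique(ratios$morphotype)) == 2L)
    welch_test(ratios$ratio[ratios$morphotype == "SFM"],
               ratios$ratio[ratios$morphotype == "FFM"]) else NULL

  dk <- profiles[profiles$condition == "dark" & profiles$depth_mm >= 0, ]
  depth_cmp <- grouped_depth_compare(dk[dk$morphotype == "SFM", ],
                                     dk[dk$morphotype == "FFM", ],
                                     bin_mm = bin_mm)
  wall_cmp <- NULL
  wd <- dk[!is.na(dk$wall_distance_mm), ]
  if (nrow(wd) > 0L && length(unique(wd$wall_distance_mm)) >= 2L) {
    near <- wd$wall_distance_mm <= stats::median(unique(wd$wall_distance_mm))
    wall_cmp <- grouped_depth_compare(wd[near, ], wd[!near, ],
                                      bin_mm = bin_mm)
  }
  list(brown_forsythe_dark = bf_dark, brown_forsythe_light = bf_light,
       ratios = ratios, light_dark_welch = ldw, depth_compare = depth_cmp,
       wall_compare = wall_cmp)
}
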