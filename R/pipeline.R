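# End-to-end orchestration: track -> qc -> metrics -> stats, with every
# threshold recorded in a machine-readable run log. QC-excluded flies are
# dropped from analytics with a logged notice.

#' Tidy per-fly binned table for a set of trajectories
#'
#' @param trajs list of `fly_trajectory`.
#' @param geom an `arena_geometry`.
#' @param what `"activity"` (moving-pair fraction) or `"occupancy"`
#'   (patch-ROI fraction; uses the physical patch if present, else the
#'   virtual patch of each fly's sector).
#' @param bin_width_s bin width.
#' @param align,stationary_threshold_px see [activity_binned()] /
#'   [motion_flags()].
#' @return data.frame: fly_id, group, bin_start, value, n_defined.
#' @export
fly_bin_table <- function(trajs, geom, what = c("activity", "occupancy"),
                          bin_width_s = 300, align = "start",
                          stationary_threshold_px = 2) {
  what <- match.arg(what)
  rois <- if (length(geom$patch_rois) > 0) geom$patch_rois else geom$virtual_patch_rois
  do.call(rbind, lapply(trajs, function(tr) {
    ser <- if (what == "activity") {
      flags <- motion_flags(displacement_series(tr, geom),
                            stationary_threshold_px)
      activity_binned(flags, bin_width_s, align = align,
                      start_clock = tr$start_clock)
    } else {
      occupancy_fraction(tr, geom, rois[[tr$sector_id + 1L]], bin_width_s,
                         align = align, start_clock = tr$start_clock)
    }
    cbind(data.frame(fly_id = tr$fly_id, group = tr$group,
                     stringsAsFactors = FALSE), ser)
  }))
}

#' Per-fly displacement-class summary
#'
#' @param trajs list of `fly_trajectory`.
#' @param geom an `arena_geometry`.
#' @param time_window NULL, elapsed, or clock window.
#' @param stationary_threshold_px stationarity floor in px.
#' @return data.frame: fly_id, group, short (P of 0.1-2 mm moves), long
#'   (P of 5-10 mm moves), n_moving.
#' @export
fly_displacement_classes <- function(trajs, geom, time_window = NULL,
                                     stationary_threshold_px = 2) {
  do.call(rbind, lapply(trajs, function(tr) {
    disp <- displacement_series(tr, geom)
    flags <- motion_flags(disp, stationary_threshold_px)
    h <- displacement_histogram(disp, flags, time_window,
                                start_clock = tr$start_clock)
    data.frame(fly_id = tr$fly_id, group = tr$group,
               short = h$short, long = h$long, n_moving = h$n,
               stringsAsFactors = FALSE)
  }))
}

#' Per-fly log2 stop-duration counts
#'
#' @inheritParams fly_displacement_classes
#' @param min_stop_duration_s shortest stop retained.
#' @param roi optional `arena_roi` restricting stop locations.
#' @param max_k highest log2 bin (shared across flies).
#' @return data.frame: fly_id, group, k, count.
#' @export
fly_stop_counts <- function(trajs, geom, time_window = NULL, roi = NULL,
                            min_stop_duration_s = 2,
                            stationary_threshold_px = 2, max_k = 6) {
  do.call(rbind, lapply(trajs, function(tr) {
    flags <- motion_flags(displacement_series(tr, geom),
                          stationary_threshold_px)
    stops <- find_stops(flags, tr, min_stop_duration_s)
    h <- stop_histogram_log2(stops, time_window, roi = roi, geom = geom,
                             dt = tr$dt, start_clock = tr$start_clock,
                             max_k = max_k)
    cbind(data.frame(fly_id = tr$fly_id, group = tr$group,
                     stringsAsFactors = FALSE), h)
  }))
}

#' Group mean +/- SEM plot of a binned series
#'
#' In clock alignment the subjective night (21:00-07:00) is shaded.
#'
#' @param df per-fly table from [fly_bin_table()].
#' @param ylab y label.
#' @param comparison optional [compare_bins()] result; significant bins are
#'   marked with a horizontal bar.
#' @param clock whether `bin_start` is clock seconds.
#' @param file optional output figure path.
#' @return ggplot object.
#' @export
plot_binned <- function(df, ylab = "value", comparison = NULL,
                        clock = FALSE, file = NULL) {
  agg <- aggregate_bins(df)
  agg$t_h <- agg$bin_start / 3600
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$t_h, y = .data$mean,
                                         colour = .data$group,
                                         fill = .data$group))
  if (clock)
    p <- p + ggplot2::annotate("rect", xmin = 21, xmax = 24, ymin = -Inf,
                               ymax = Inf, alpha = 0.12) +
      ggplot2::annotate("rect", xmin = 0, xmax = 7, ymin = -Inf, ymax = Inf,
                        alpha = 0.12)
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = if (clock) "time of day (h)" else "time (h)",
                  y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(comparison) && any(comparison$significant)) {
    ytop <- max(agg$mean + ifelse(is.na(agg$sem), 0, agg$sem), na.rm = TRUE)
    sig <- comparison[comparison$significant, , drop = FALSE]
    p <- p + ggplot2::annotate("segment",
                               x = sig$bin_start / 3600,
                               xend = (sig$bin_start + diff(sort(unique(comparison$bin_start)))[1] %||% 300) / 3600,
                               y = ytop * 1.05, yend = ytop * 1.05,
                               colour = "black", linewidth = 1)
  }
  if (!is.null(file)) { save_figure(p, file); return(invisible(p)) }
  p
}

#' Run the full pipeline on a recording
#'
#' Executes tracking, quality control, behavioural metrics and (when both
#' groups are present) per-bin group statistics; writes trajectory CSV, QC
#' report, analytics tables, comparison tables, figures and a JSON run log
#' of every threshold used.
#'
#' @param manifest a manifest path or list (see [read_manifest()]). Optional
#'   analysis fields: `max_error_rate` (0.05), `jump_threshold_mm` (10),
#'   `stationary_threshold_px` (2), `bin_width_s` (300),
#'   `occupancy_bin_s` (1800), `align` ("start"), `min_stop_duration_s` (2),
#'   `threshold` (segmentation; NULL = automatic), `alpha` (0.05).
#' @return list: trajectories, qc, retained, activity, occupancy, stops,
#'   classes, comparisons, log (all also written under `out_dir`).
#' @export
run_pipeline <- function(manifest) {
  m <- read_manifest(manifest)
  cfg <- list(max_error_rate = m$max_error_rate %||% 0.05,
              jump_threshold_mm = m$jump_threshold_mm %||% 10,
              stationary_threshold_px = m$stationary_threshold_px %||% 2,
              bin_width_s = m$bin_width_s %||% 300,
              occupancy_bin_s = m$occupancy_bin_s %||% 1800,
              align = m$align %||% "start",
              min_stop_duration_s = m$min_stop_duration_s %||% 2,
              alpha = m$alpha %||% 0.05)
  out <- m$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  geom <- m$geom

  tracked <- track_frames(m$frames, geom, metadata = m$metadata,
                          threshold = m$threshold)
  trajs <- tracked$trajectories
  write_trajectory_csv(trajs, file.path(out, "trajectories.csv"))

  qc <- qc_report(trajs, geom, cfg$max_error_rate, cfg$jump_threshold_mm)
  write.csv(qc, file.path(out, "qc_report.csv"), row.names = FALSE)
  plot_traces(trajs, geom, file.path(out, "traces.png"))
  retained <- apply_exclusion(qc, cfg$max_error_rate)
  dropped <- setdiff(qc$fly_id, retained$fly_id)
  notices <- character(0)
  if (length(dropped) > 0)
    notices <- c(notices, paste("QC-excluded flies dropped from analytics:",
                                paste(dropped, collapse = ", ")))
  keep <- trajs[vapply(trajs, function(t) t$fly_id %in% retained$fly_id,
                       logical(1))]

  res <- list(trajectories = trajs, qc = qc, retained = retained,
              log = c(cfg, list(segmentation_threshold = tracked$threshold,
                                notices = notices)))
  if (length(keep) == 0) {
    res$log$notices <- c(notices, "all flies excluded by QC; analytics skipped")
    jsonlite::write_json(res$log, file.path(out, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(res)
  }

  res$activity <- fly_bin_table(keep, geom, "activity", cfg$bin_width_s,
                                cfg$align, cfg$stationary_threshold_px)
  res$occupancy <- fly_bin_table(keep, geom, "occupancy", cfg$occupancy_bin_s,
                                 cfg$align)
  res$stops <- fly_stop_counts(keep, geom,
                               min_stop_duration_s = cfg$min_stop_duration_s,
                               stationary_threshold_px = cfg$stationary_threshold_px)
  res$classes <- fly_displacement_classes(keep, geom,
                                          stationary_threshold_px = cfg$stationary_threshold_px)
  write.csv(res$activity, file.path(out, "activity.csv"), row.names = FALSE)
  write.csv(res$occupancy, file.path(out, "occupancy.csv"), row.names = FALSE)
  write.csv(res$stops, file.path(out, "stop_counts.csv"), row.names = FALSE)
  write.csv(res$classes, file.path(out, "displacement_classes.csv"),
            row.names = FALSE)

  groups <- unique(vapply(keep, `[[`, character(1), "group"))
  both <- all(c("pre-fed", "pre-starved") %in% groups)
  if (both) {
    sa <- res$activity[res$activity$group == "pre-fed", ]
    sb <- res$activity[res$activity$group == "pre-starved", ]
    res$comparisons <- list(
      activity = compare_bins(sa, sb, cfg$alpha),
      occupancy = compare_bins(res$occupancy[res$occupancy$group == "pre-fed", ],
                               res$occupancy[res$occupancy$group == "pre-starved", ],
                               cfg$alpha))
    write.csv(res$comparisons$activity,
              file.path(out, "comparison_activity.csv"), row.names = FALSE)
    write.csv(res$comparisons$occupancy,
              file.path(out, "comparison_occupancy.csv"), row.names = FALSE)
  }
  plot_binned(res$activity, "activity (moving fraction)",
              comparison = res$comparisons$activity,
              clock = cfg$align == "clock",
              file = file.path(out, "activity.png"))
  plot_binned(res$occupancy, "patch occupancy",
              comparison = res$comparisons$occupancy,
              clock = cfg$align == "clock",
              file = file.path(out, "occupancy.png"))

  jsonlite::write_json(res$log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res
}
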