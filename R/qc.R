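# Quality control: missing-detection rate with a hard exclusion threshold,
# and flagging (never deletion) of implausibly long frame-to-frame jumps for
# human inspection.

#' Fraction of frames without a detection
#' @param traj a `fly_trajectory`.
#' @return missing rate in \[0, 1\].
#' @export
missing_rate <- function(traj) {
  n <- n_frames(traj)
  if (n == 0) stop("trajectory has zero frames")
  sum(!traj$valid) / n
}

#' Flag long frame-to-frame jumps
#'
#' Lists every consecutive valid-valid frame pair whose displacement exceeds
#' the threshold. Jumps are flagged for inspection only, never removed:
#' a long apparent move may be a false-positive detection.
#'
#' @param traj a `fly_trajectory`.
#' @param geom an `arena_geometry` (for the mm conversion).
#' @param jump_threshold_mm flag displacements strictly above this (default
#'   10 mm/frame, about four times a fast walk at 1 Hz).
#' @return data.frame: frame (first frame of the pair), displacement_mm.
#' @export
flag_jumps <- function(traj, geom, jump_threshold_mm = 10) {
  if (jump_threshold_mm <= 0) stop("jump threshold must be > 0")
  disp <- displacement_series(traj, geom)
  hit <- which(disp$defined & disp$mm > jump_threshold_mm)
  data.frame(frame = hit, displacement_mm = disp$mm[hit])
}

#' Per-trajectory quality-control report
#'
#' @param trajs a `fly_trajectory` or list of them.
#' @param geom an `arena_geometry`.
#' @param max_error_rate exclusion threshold on the missing rate; strictly
#'   greater rates are excluded ("more than" semantics: exactly 5% is kept).
#' @param jump_threshold_mm see [flag_jumps()].
#' @return data.frame (class `qc_report`): fly_id, sector, group,
#'   missing_rate, excluded, n_jumps; jump details in attribute `jumps`.
#' @export
qc_report <- function(trajs, geom, max_error_rate = 0.05,
                      jump_threshold_mm = 10) {
  if (inherits(trajs, "fly_trajectory")) trajs <- list(trajs)
  jumps <- lapply(trajs, flag_jumps, geom = geom,
                  jump_threshold_mm = jump_threshold_mm)
  rep <- data.frame(
    fly_id = vapply(trajs, `[[`, character(1), "fly_id"),
    sector = vapply(trajs, `[[`, integer(1), "sector_id"),
    group = vapply(trajs, `[[`, character(1), "group"),
    missing_rate = vapply(trajs, missing_rate, numeric(1)),
    n_jumps = vapply(jumps, nrow, integer(1)),
    stringsAsFactors = FALSE)
  rep$excluded <- rep$missing_rate > max_error_rate
  attr(rep, "jumps") <- jumps
  attr(rep, "max_error_rate") <- max_error_rate
  attr(rep, "jump_threshold_mm") <- jump_threshold_mm
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Apply the missing-rate exclusion rule
#'
#' Retains reports whose missing rate does not exceed `max_error_rate`;
#' rates strictly above are excluded (a rate of exactly the threshold is
#' retained). Also computes an experiment-level roll-up: the whole recording
#' fails if the mean missing rate across flies exceeds the threshold.
#'
#' @param reports a `qc_report` data.frame (or any data.frame with a
#'   `missing_rate` column).
#' @param max_error_rate threshold, default 0.05.
#' @return the retained subset; attributes `experiment_mean_rate` and
#'   `experiment_excluded` carry the roll-up.
#' @export
apply_exclusion <- function(reports, max_error_rate = 0.05) {
  keep <- reports[reports$missing_rate <= max_error_rate, , drop = FALSE]
  mean_rate <- if (nrow(reports) > 0) mean(reports$missing_rate) else NA_real_
  attr(keep, "experiment_mean_rate") <- mean_rate
  attr(keep, "experiment_excluded") <-
    !is.na(mean_rate) && mean_rate > max_error_rate
  keep
}

#' Plot walking traces with a temporal colour code
#'
#' One panel per occupied sector; the path polyline is coloured by elapsed
#' time and breaks at invalid frames, over the sector's radial band outline.
#'
#' @param trajs a `fly_trajectory` or list of them.
#' @param geom an `arena_geometry`.
#' @param file output figure path (`.png`, `.pdf` or `.svg`); NULL returns
#'   the ggplot object without writing.
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_traces <- function(trajs, geom, file = NULL) {
  if (inherits(trajs, "fly_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr) {
    run <- cumsum(!tr$valid)  # breaks the polyline at gaps
    data.frame(fly = sprintf("%s (sector %d, %s)", tr$fly_id, tr$sector_id, tr$group),
               t_h = (seq_along(tr$x) - 1) * tr$dt / 3600,
               x = tr$x, y = tr$y, seg = run)
  }))
  dfv <- df[!is.na(df$x), , drop = FALSE]
  if (nrow(dfv) == 0) {             # e.g. an all-invalid trajectory
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no valid frames") +
      ggplot2::theme_void()
    if (is.null(file)) return(p)
    save_figure(p, file)
    return(invisible(p))
  }
  p <- ggplot2::ggplot(dfv,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$t_h, group = .data$seg)) +
    ggplot2::geom_path(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_viridis_c(name = "time (h)") +
    ggplot2::facet_wrap(~fly) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (is.null(file)) return(p)
  save_figure(p, file)
  invisible(p)
}

# device-agnostic figure writer
save_figure <- function(p, file, width = 8, height = 6) {
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(file)
}
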