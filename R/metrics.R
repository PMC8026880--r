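# Behavioural analytics at 1 Hz: frame-pair displacements as a velocity
# proxy, a hard stationarity floor against camera noise, binned activity,
# maximal stop bouts on a log2 duration axis, displacement distributions
# with short/long walk classes, and ROI occupancy. Undefined (missed-
# detection) frames propagate: nothing is interpolated.

#' Frame-pair displacement series
#'
#' Euclidean centroid displacement per consecutive frame pair, defined only
#' when both frames are valid; never interpolated across gaps.
#'
#' @param traj a `fly_trajectory`.
#' @param geom an `arena_geometry` (mm conversion).
#' @return a `displacement_series`: `px`, `mm` (NA where undefined),
#'   `defined` (logical), `dt`; length `n_frames - 1`. Pair `i` spans frames
#'   `i` and `i + 1`.
#' @export
displacement_series <- function(traj, geom) {
  n <- n_frames(traj)
  dx <- diff(traj$x); dy <- diff(traj$y)
  px <- sqrt(dx^2 + dy^2)
  defined <- traj$valid[-n] & traj$valid[-1]
  px[!defined] <- NA_real_
  structure(list(px = px, mm = px * geom$pixel_scale, defined = defined,
                 dt = traj$dt), class = "displacement_series")
}

#' Classify frame pairs as moving or stationary
#'
#' Displacements below the stationarity floor are treated as camera noise:
#' the animal is stationary. The floor is inclusive on the moving side
#' (a displacement of exactly the threshold counts as movement).
#'
#' @param disp a `displacement_series`.
#' @param stationary_threshold_px floor in px (default 2 px = 0.1 mm at the
#'   default calibration).
#' @return a `motion_flags`: `moving`, `defined` (moving implies defined),
#'   `dt`.
#' @export
motion_flags <- function(disp, stationary_threshold_px = 2) {
  if (stationary_threshold_px <= 0) stop("threshold must be > 0")
  moving <- disp$defined & !is.na(disp$px) & disp$px >= stationary_threshold_px
  structure(list(moving = moving, defined = disp$defined, dt = disp$dt),
            class = "motion_flags")
}

# elapsed time (s) of the start of pair/frame i (1-based)
elapsed_of <- function(i, dt) (i - 1) * dt

# window predicate over elapsed seconds; `window` is NULL (all), numeric
# c(start_s, end_s) in elapsed time, or character c("HH:MM","HH:MM") in
# wall-clock time (requires start_clock); half-open [start, end)
in_window <- function(elapsed_s, window, start_clock = NA) {
  if (is.null(window)) return(rep(TRUE, length(elapsed_s)))
  if (is.character(window)) {
    if (is.na(start_clock)) stop("clock window requires start_clock")
    w <- parse_clock(window)
    clk <- (start_clock + elapsed_s) %% 86400
    if (w[2] >= w[1]) clk >= w[1] & clk < w[2]
    else clk >= w[1] | clk < w[2]          # wraps midnight
  } else {
    elapsed_s >= window[1] & elapsed_s < window[2]
  }
}

#' Per-bin activity (fraction of moving frame pairs)
#'
#' @param flags a `motion_flags`.
#' @param bin_width_s bin width in seconds (default 300 = 5 min).
#' @param align `"start"` (t = 0 at the first frame; trailing partial bin
#'   dropped) or `"clock"` (bins anchored to midnight on the wall clock;
#'   needs `start_clock`).
#' @param start_clock seconds since midnight (or "HH:MM").
#' @return data.frame: `bin_start` (elapsed s, or clock s in clock mode),
#'   `value` (moving / defined pairs; NA if no defined pairs), `n_defined`.
#' @export
activity_binned <- function(flags, bin_width_s = 300, align = "start",
                            start_clock = NA) {
  tt <- elapsed_of(seq_along(flags$moving), flags$dt)
  bin_stats(tt, value = flags$moving, defined = flags$defined,
            bin_width_s = bin_width_s, align = align,
            start_clock = start_clock, statistic = "mean")
}

# shared binning core: per bin, mean (or sum) of `value` over defined points
bin_stats <- function(tt, value, defined, bin_width_s, align, start_clock,
                      statistic = "mean") {
  if (align == "clock") {
    sc <- if (is.character(start_clock)) parse_clock(start_clock) else start_clock
    if (is.na(sc)) stop("clock alignment requires start_clock")
    bins <- floor(((sc + tt) %% 86400) / bin_width_s) * bin_width_s
  } else {
    bins <- floor(tt / bin_width_s) * bin_width_s
    dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
    covered <- max(tt) + dt           # end of the last sampled interval
    bins[bins + bin_width_s > covered + 1e-9] <- NA  # drop trailing partial bin
  }
  ok <- !is.na(bins)
  ub <- sort(unique(bins[ok]))
  nd <- vapply(ub, function(b) sum(defined[ok & bins == b]), numeric(1))
  val <- vapply(ub, function(b) {
    i <- ok & bins == b & defined
    if (!any(i)) return(NA_real_)
    if (statistic == "mean") mean(value[i]) else sum(value[i])
  }, numeric(1))
  data.frame(bin_start = ub, value = val, n_defined = nd)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Find maximal stop events
#'
#' A stop is a maximal run of stationary, defined frame pairs; runs are
#' broken by undefined pairs (a gap never extends a stop) and runs shorter
#' than `min_stop_duration_s` are discarded — the stop-duration axis starts
#' at the 2-3 s bin. The event location is the mean position over the
#' frames the run spans.
#'
#' @param flags a `motion_flags`.
#' @param traj the `fly_trajectory` the flags came from.
#' @param min_stop_duration_s minimum duration retained (default 2 s).
#' @return data.frame: start_frame, duration_s, x, y.
#' @export
find_stops <- function(flags, traj, min_stop_duration_s = 2) {
  code <- ifelse(!flags$defined, -1L, ifelse(flags$moving, 0L, 1L))
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L & r$lengths * flags$dt >= min_stop_duration_s
  if (!any(keep))
    return(data.frame(start_frame = integer(0), duration_s = numeric(0),
                      x = numeric(0), y = numeric(0)))
  sf <- starts[keep]; len <- r$lengths[keep]
  pos <- t(mapply(function(p, l) {
    fr <- p:(p + l)   # frames spanned by pairs p..p+l-1
    c(mean(traj$x[fr]), mean(traj$y[fr]))
  }, sf, len))
  data.frame(start_frame = sf, duration_s = len * flags$dt,
             x = pos[, 1], y = pos[, 2])
}

#' ROI membership of stop events (by mean event position)
#' @param stops data.frame from [find_stops()].
#' @param geom an `arena_geometry`.
#' @param roi an `arena_roi`.
#' @return logical per stop.
#' @export
stops_in_roi <- function(stops, geom, roi) {
  if (nrow(stops) == 0) return(logical(0))
  point_in_roi(geom, roi, cbind(stops$x, stops$y))
}

#' Stop-duration histogram on a log2 axis
#'
#' Bin `k` (k >= 1) counts stops of duration 2^k to 2^(k+1) - 1 seconds
#' (so k = 1 is 2-3 s, k = 2 is 4-7 s, ...), restricted to stops starting
#' inside `time_window` and, if an ROI is given, located inside it.
#'
#' @param stops data.frame from [find_stops()].
#' @param time_window NULL, elapsed c(start_s, end_s), or clock
#'   c("HH:MM", "HH:MM").
#' @param roi optional `arena_roi`; with `geom`, restricts to stops whose
#'   location is inside.
#' @param geom required when `roi` is given.
#' @param dt frame interval (s) used for stop start times.
#' @param start_clock needed for clock windows.
#' @param max_k highest bin; defaults to the largest observed duration.
#' @return data.frame: k, duration_range, count.
#' @export
stop_histogram_log2 <- function(stops, time_window = NULL, roi = NULL,
                                geom = NULL, dt = 1, start_clock = NA,
                                max_k = NULL) {
  sel <- rep(TRUE, nrow(stops))
  if (nrow(stops) > 0) {
    sel <- in_window(elapsed_of(stops$start_frame, dt), time_window, start_clock)
    if (!is.null(roi)) {
      if (is.null(geom)) stop("roi filtering requires geom")
      sel <- sel & stops_in_roi(stops, geom, roi)
    }
  }
  d <- stops$duration_s[sel]
  if (is.null(max_k)) max_k <- if (length(d) > 0) max(1, floor(log2(max(d)))) else 1
  k <- seq_len(max_k)
  counts <- vapply(k, function(kk) sum(d >= 2^kk & d < 2^(kk + 1)), numeric(1))
  data.frame(k = k,
             duration_range = sprintf("%d-%d s", 2^k, 2^(k + 1) - 1),
             count = counts)
}

#' Displacement distribution and walk classes
#'
#' Normalised histogram of defined, moving displacements in a window, plus
#' the two walk classes: short-distance walks (0.1-2 mm; the lower bound is
#' the stationarity floor, sub-threshold jitter belongs to neither class)
#' and long-distance walks (5-10 mm), both inclusive at both ends.
#'
#' @param disp a `displacement_series`.
#' @param flags a `motion_flags` aligned to `disp` (default: 2 px floor).
#' @param time_window NULL, elapsed, or clock window (see
#'   [stop_histogram_log2()]).
#' @param bin_width_mm,max_mm histogram grid; values above `max_mm` fall in
#'   the top bin.
#' @param start_clock needed for clock windows.
#' @return list: `breaks` (mm), `prob` (sums to 1; NA if no moving pairs),
#'   `short`, `long` (class probabilities), `n` (moving pairs used).
#' @export
displacement_histogram <- function(disp, flags = motion_flags(disp),
                                   time_window = NULL, bin_width_mm = 0.5,
                                   max_mm = 15, start_clock = NA) {
  sel <- flags$moving &
    in_window(elapsed_of(seq_along(disp$mm), disp$dt), time_window, start_clock)
  v <- disp$mm[sel]
  breaks <- seq(0, max_mm, by = bin_width_mm)
  if (length(v) == 0)
    return(list(breaks = breaks, prob = rep(NA_real_, length(breaks) - 1),
                short = NA_real_, long = NA_real_, n = 0L))
  cuts <- pmin(pmax(ceiling(v / bin_width_mm), 1L), length(breaks) - 1L)
  counts <- tabulate(cuts, nbins = length(breaks) - 1L)
  list(breaks = breaks, prob = counts / length(v),
       short = mean(v >= 0.1 & v <= 2),
       long = mean(v >= 5 & v <= 10),
       n = length(v))
}

#' Per-bin ROI occupancy
#'
#' Fraction of valid frames per time bin whose position lies inside the ROI
#' (physical food patch or same-sized virtual patch — identical machinery).
#'
#' @param traj a `fly_trajectory`.
#' @param geom an `arena_geometry`.
#' @param roi an `arena_roi`.
#' @param bin_width_s bin width (default 1800 s = 30 min).
#' @param align,start_clock see [activity_binned()].
#' @return data.frame: bin_start, value (NA where no valid frames),
#'   n_defined (valid frames in bin).
#' @export
occupancy_fraction <- function(traj, geom, roi, bin_width_s = 1800,
                               align = "start", start_clock = traj$start_clock) {
  inroi <- rep(FALSE, n_frames(traj))
  v <- which(traj$valid)
  if (length(v) > 0)
    inroi[v] <- point_in_roi(geom, roi, cbind(traj$x[v], traj$y[v]))
  tt <- elapsed_of(seq_len(n_frames(traj)), traj$dt)
  bin_stats(tt, value = inroi, defined = traj$valid,
            bin_width_s = bin_width_s, align = align,
            start_clock = start_clock, statistic = "mean")
}

#' Re-align a binned series from elapsed time to the wall clock
#'
#' `mode = "start"` returns the series unchanged (t = 0 at the first
#' frame). `mode = "clock"` maps each bin's start to its time of day, so
#' series from flies started at different times co-bin on a shared clock
#' axis (exact when starts lie on the bin grid).
#'
#' @param series data.frame with a `bin_start` column in elapsed seconds.
#' @param start_clock "HH:MM" or seconds since midnight; required for clock
#'   mode.
#' @param mode `"start"` or `"clock"`.
#' @param bin_width_s the series' bin width (for snapping to the clock grid).
#' @return the series with `bin_start` re-labelled (clock seconds).
#' @export
align_series <- function(series, start_clock = NA, mode = c("start", "clock"),
                         bin_width_s = NULL) {
  mode <- match.arg(mode)
  if (mode == "start") return(series)
  sc <- if (is.character(start_clock)) parse_clock(start_clock) else start_clock
  if (is.na(sc)) stop("clock alignment requires start_clock")
  if (is.null(bin_width_s))
    bin_width_s <- min(diff(sort(unique(series$bin_start)))) %||% 1
  series$bin_start <- floor(((sc + series$bin_start) %% 86400) /
                              bin_width_s) * bin_width_s
  series
}

#' Time budget over frame pairs
#'
#' Moving, stopped and undefined time partition the recording's pair time
#' exactly.
#'
#' @param flags a `motion_flags`.
#' @return list: moving_s, stopped_s, undefined_s, total_s.
#' @export
time_budget <- function(flags) {
  dt <- flags$dt
  list(moving_s = sum(flags$moving) * dt,
       stopped_s = sum(flags$defined & !flags$moving) * dt,
       undefined_s = sum(!flags$defined) * dt,
       total_s = length(flags$moving) * dt)
}

#' Aggregate a per-fly binned table into group mean / SEM / n
#'
#' @param df data.frame with columns `fly_id`, `group`, `bin_start`,
#'   `value` (NA = undefined for that fly in that bin).
#' @return data.frame: group, bin_start, mean, sem, n (flies with a defined
#'   value in the bin).
#' @export
aggregate_bins <- function(df) {
  sp <- split(df, list(df$group, df$bin_start), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    v <- g$value[!is.na(g$value)]
    data.frame(group = g$group[1], bin_start = g$bin_start[1],
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  out <- out[order(out$group, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
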