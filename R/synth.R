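# Ground-truthed synthetic experiments: a two-state (stop/walk) random walker
# per sector, rendered as a dark disc on a bright backlit background. The
# generator is first-class pipeline code: every downstream stage is testable
# against the truth it emits.

#' Parameters of the stop/walk simulation
#'
#' @param p_stop_to_walk per-second probability of leaving a stop.
#' @param p_walk_to_stop per-second probability of stopping.
#' @param speed_log_mean,speed_log_sd log-normal parameters of the per-second
#'   step length in mm (meanlog / sdlog).
#' @param turn_sd SD (radians) of the wrapped-normal heading change per step.
#' @param patch_attraction weight >= 0 mixing a patch-pointing unit vector
#'   into the heading; 0 = no attraction.
#' @param dropout_rate per-frame probability the detection is missing.
#' @param noise_sd additive Gaussian pixel noise, grayscale units (0-255).
#' @param fly_radius rendered body radius in mm.
#' @param seed optional integer; when set, the simulation is reproducible.
#' @return a `walk_params` list.
#' @export
walk_params <- function(p_stop_to_walk = 0.2, p_walk_to_stop = 0.2,
                        speed_log_mean = log(2), speed_log_sd = 0.5,
                        turn_sd = 0.6, patch_attraction = 0,
                        dropout_rate = 0, noise_sd = 0,
                        fly_radius = 1.2, seed = NULL) {
  p <- list(p_stop_to_walk = p_stop_to_walk, p_walk_to_stop = p_walk_to_stop,
            speed_log_mean = speed_log_mean, speed_log_sd = speed_log_sd,
            turn_sd = turn_sd, patch_attraction = patch_attraction,
            dropout_rate = dropout_rate, noise_sd = noise_sd,
            fly_radius = fly_radius, seed = seed)
  for (nm in c("p_stop_to_walk", "p_walk_to_stop"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (p$dropout_rate < 0 || p$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (!is.finite(p$speed_log_mean) || !is.finite(p$speed_log_sd) ||
      p$speed_log_sd < 0) stop("speed parameters must be finite")
  if (p$patch_attraction < 0) stop("patch_attraction must be >= 0")
  if (p$fly_radius <= 0) stop("fly_radius must be > 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(p, class = "walk_params")
}

#' Shipped behavioural presets for the two experimental groups
#'
#' "pre-fed": faster walker (more 5-10 mm steps), no patch attraction.
#' "pre-starved": slower walker (more <= 2 mm steps), stops more, attracted
#' to the food patch. Directions mirror satiety-dependent locomotion;
#' magnitudes are the generator's own choices.
#'
#' @return named list of two `walk_params` ("pre-fed", "pre-starved").
#' @export
group_presets <- function() {
  list(
    "pre-fed" = walk_params(p_stop_to_walk = 0.30, p_walk_to_stop = 0.15,
                            speed_log_mean = log(4), speed_log_sd = 0.45,
                            patch_attraction = 0),
    "pre-starved" = walk_params(p_stop_to_walk = 0.15, p_walk_to_stop = 0.30,
                                speed_log_mean = log(1.1), speed_log_sd = 0.45,
                                patch_attraction = 0.8)
  )
}

# fold v into [lo, hi] by mirror reflection
reflect_into <- function(v, lo, hi) {
  if (hi <= lo) return(rep((lo + hi) / 2, length(v)))
  rng <- hi - lo
  t <- (v - lo) %% (2 * rng)
  ifelse(t > rng, 2 * rng - t, t) + lo
}

# uniform point in the annular wedge of sector `sr`, with radial/angular
# margin `m_px` so a disc of that radius stays inside
runif_in_sector <- function(geom, sr, m_px = 0) {
  r <- sqrt(runif(1, (sr$r_in_px + m_px)^2, (sr$r_out_px - m_px)^2))
  am <- m_px / r
  th <- runif(1, sr$theta0 + am, sr$theta1 - am)
  geom$center + r * c(cos(th), sin(th))
}

#' Simulate one stop/walk trajectory confined to a sector
#'
#' Two-state Markov chain at `dt` resolution: in the walk state the animal
#' advances by a log-normal step along a persistent heading (previous heading
#' plus a wrapped-normal turn, optionally mixed with a unit vector pointing
#' at the sector's patch, weighted by `patch_attraction`); in the stop state
#' the position is unchanged. Walls reflect: a step leaving the sector is
#' folded back by mirror reflection in the radial and angular coordinates.
#'
#' @param params a [walk_params()] object.
#' @param geom an `arena_geometry` with wedge sectors.
#' @param sector_id sector to confine the walker to (0-based).
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval in seconds (default 1, the acquisition rate).
#' @return a `ground_truth` object: `x`, `y` (px), `state`
#'   (`"stop"`/`"walk"` per frame), `dropout` (logical per frame),
#'   `sector_id`, `dt`, `params`.
#' @export
simulate_trajectory <- function(params, geom, sector_id, n_frames, dt = 1) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (sector_id < 0 || sector_id >= geom$n_sectors) stop("no such sector")
  if (!is.null(geom$label_mask))
    stop("simulation requires a wedge-sector geometry")
  if (!is.null(params$seed)) set.seed(params$seed)
  sr <- geom$sector_regions[[sector_id + 1L]]
  m_px <- params$fly_radius / geom$pixel_scale
  patch <- NULL
  rois <- if (length(geom$patch_rois) > 0) geom$patch_rois else geom$virtual_patch_rois
  if (params$patch_attraction > 0 && length(rois) > 0)
    patch <- rois[[sector_id + 1L]]$center

  x <- numeric(n_frames); y <- numeric(n_frames)
  walking <- logical(n_frames)
  pos <- runif_in_sector(geom, sr, m_px)
  heading <- runif(1, 0, 2 * pi)
  # start state drawn from the chain's stationary distribution
  p_walk_stat <- params$p_stop_to_walk /
    max(params$p_stop_to_walk + params$p_walk_to_stop, .Machine$double.eps)
  state_walk <- runif(1) < p_walk_stat
  step_px_all <- rlnorm(n_frames, params$speed_log_mean, params$speed_log_sd) *
    dt / geom$pixel_scale
  turn_all <- rnorm(n_frames, 0, params$turn_sd)
  u_all <- runif(2 * n_frames)

  for (t in seq_len(n_frames)) {
    x[t] <- pos[1]; y[t] <- pos[2]; walking[t] <- state_walk
    # transition for the next frame
    state_walk <- if (state_walk) u_all[2 * t - 1] >= params$p_walk_to_stop
                  else u_all[2 * t - 1] < params$p_stop_to_walk
    if (t == n_frames) break
    if (walking[t]) {
      heading <- heading + turn_all[t]
      ux <- cos(heading); uy <- sin(heading)
      if (!is.null(patch)) {
        d <- patch - pos
        nrm <- sqrt(sum(d^2))
        if (nrm > 1e-9) {
          ux <- ux + params$patch_attraction * d[1] / nrm
          uy <- uy + params$patch_attraction * d[2] / nrm
        }
      }
      ang <- atan2(uy, ux)
      prop <- pos + step_px_all[t] * c(cos(ang), sin(ang))
      # reflect into the sector (polar mirror, with body-radius margin)
      dp <- prop - geom$center
      r <- sqrt(sum(dp^2)); th <- atan2(dp[2], dp[1]) %% (2 * pi)
      # unwrap theta near the wedge for sectors spanning the 0/2pi seam
      if (th < sr$theta0 - pi) th <- th + 2 * pi
      if (th > sr$theta1 + pi) th <- th - 2 * pi
      r <- reflect_into(r, sr$r_in_px + m_px, sr$r_out_px - m_px)
      am <- m_px / r
      th <- reflect_into(th, sr$theta0 + am, sr$theta1 - am)
      newpos <- geom$center + r * c(cos(th), sin(th))
      mv <- newpos - pos
      if (sum(mv^2) > 1e-12) heading <- atan2(mv[2], mv[1])
      pos <- newpos
    }
  }
  dropout <- runif(n_frames) < params$dropout_rate
  structure(list(x = x, y = y,
                 state = ifelse(walking, "walk", "stop"),
                 dropout = dropout, sector_id = as.integer(sector_id),
                 dt = dt, params = params),
            class = "ground_truth")
}

# grayscale levels of the rendered scene, in [0, 1]
.render_levels <- list(outside = 0.35, field = 0.85, wall = 0.45, fly = 0.12)

#' Render the empty-arena background image
#'
#' Bright backlit field inside the dish, darker walls (annulus edges and
#' sector spokes), dark outside the dish.
#'
#' @param geom an `arena_geometry`.
#' @return numeric matrix in \[0, 1\], dim (image_height, image_width).
#' @export
render_background <- function(geom) {
  if (!is.null(geom$.cache$background)) return(geom$.cache$background)
  lv <- .render_levels
  if (!is.null(geom$label_mask)) {
    bg <- matrix(lv$outside, geom$image_height, geom$image_width)
    bg[geom$label_mask > 0] <- lv$field
    geom$.cache$background <- bg
    return(bg)
  }
  x <- matrix(seq_len(geom$image_width), geom$image_height,
              geom$image_width, byrow = TRUE)
  y <- matrix(seq_len(geom$image_height), geom$image_height, geom$image_width)
  pol <- polar_about_center(geom, x, y)
  sr1 <- geom$sector_regions[[1]]
  w2 <- (geom$wall_mm / geom$pixel_scale) / 2
  bg <- matrix(lv$outside, geom$image_height, geom$image_width)
  bg[pol$r <= sr1$r_out_px] <- lv$field
  wall <- abs(pol$r - sr1$r_in_px) < w2 | abs(pol$r - sr1$r_out_px) < w2
  if (geom$n_sectors > 1) {
    dth <- 2 * pi / geom$n_sectors
    ang_off <- pol$theta %% dth
    ang_dist <- pmin(ang_off, dth - ang_off) * pol$r
    wall <- wall | (ang_dist < w2 & pol$r >= sr1$r_in_px & pol$r <= sr1$r_out_px)
  }
  bg[wall & pol$r <= sr1$r_out_px + w2] <- lv$wall
  bg[pol$r < sr1$r_in_px - w2] <- lv$field
  geom$.cache$background <- bg
  bg
}

draw_disc <- function(img, cx, cy, r, value) {
  jr <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  ir <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xg <- matrix(jr, length(ir), length(jr), byrow = TRUE)
  yg <- matrix(ir, length(ir), length(jr))
  sub <- img[ir, jr, drop = FALSE]
  sub[(xg - cx)^2 + (yg - cy)^2 <= r^2] <- value
  img[ir, jr] <- sub
  img
}

#' Render an image sequence from ground-truth trajectories
#'
#' Each present animal (frame not in its dropout mask) is drawn as a dark
#' disc of radius `params$fly_radius` at its true position; Gaussian noise of
#' SD `params$noise_sd` (grayscale units, 0-255 scale) is added and values
#' clipped to \[0, 1\]. Dropout frames omit the animal entirely.
#'
#' @param truths list of `ground_truth` objects, at most one per sector.
#' @param geom an `arena_geometry`.
#' @param params a [walk_params()] supplying `fly_radius` and `noise_sd`.
#' @param out_dir if non-NULL, frames are written as numbered grayscale PNGs
#'   (`frame_000001.png`, ...) and file paths returned instead of matrices.
#' @return list with `frames` (list of matrices, or character paths) and
#'   `background`.
#' @export
render_frames <- function(truths, geom, params = walk_params(),
                          out_dir = NULL) {
  secs <- vapply(truths, function(tr) tr$sector_id, integer(1))
  if (anyDuplicated(secs)) stop("two trajectories share a sector")
  n_frames <- if (length(truths) > 0) length(truths[[1]]$x) else 0L
  for (tr in truths) if (length(tr$x) != n_frames)
    stop("trajectories differ in frame count")
  bg <- render_background(geom)
  r_px <- params$fly_radius / geom$pixel_scale
  sdn <- params$noise_sd / 255
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    img <- bg
    for (tr in truths) if (!tr$dropout[t])
      img <- draw_disc(img, tr$x[t], tr$y[t], r_px, .render_levels$fly)
    if (sdn > 0) {
      img <- img + matrix(rnorm(length(img), 0, sdn), nrow(img))
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    if (is.null(out_dir)) {
      out[[t]] <- img
    } else {
      f <- file.path(out_dir, sprintf("frame_%06d.png", t))
      png::writePNG(img, f)
      out[[t]] <- f
    }
  }
  list(frames = if (is.null(out_dir)) out else unlist(out), background = bg)
}

#' Generate a full two-group synthetic experiment
#'
#' Flies of the groups are assigned to alternating sectors (group 1 in
#' sector 0, group 2 in sector 1, ...), mirroring alternate placement of the
#' two feeding-state groups in the dish.
#'
#' @param presets named list of [walk_params()], one per group (default
#'   [group_presets()]).
#' @param n_flies_per_group flies per group; total must not exceed
#'   `geom$n_sectors`.
#' @param n_frames frames to simulate.
#' @param seed integer seed controlling the whole experiment.
#' @param geom an `arena_geometry`.
#' @param start_clock recording start as "HH:MM" wall-clock time.
#' @param out_dir if non-NULL, writes `frames/`, `ground_truth.csv`,
#'   `metadata.csv` and `geometry.yaml` under it.
#' @param render if FALSE (default when `out_dir` is NULL), no images are
#'   rendered; the truth and metadata alone support metric-level tests.
#' @return a `synthetic_experiment`: `truths` (list), `metadata`
#'   (data.frame: fly_id, sector, group, start_clock, occupied), `geom`,
#'   `presets`, and `frames` (paths) when rendered to disk.
#' @export
generate_experiment <- function(presets = group_presets(), n_flies_per_group = 4,
                                n_frames = 600, seed = 1,
                                geom = build_default_geometry(),
                                start_clock = "12:00",
                                out_dir = NULL, render = !is.null(out_dir)) {
  if (length(presets) != 2 || is.null(names(presets)))
    stop("presets must be a named list of two walk_params")
  n_total <- 2 * n_flies_per_group
  if (n_total > geom$n_sectors)
    stop("too many flies: ", n_total, " > ", geom$n_sectors, " sectors")
  set.seed(seed)
  groups <- rep(names(presets), times = n_flies_per_group)  # g1, g2, g1, g2, ...
  sectors <- seq_len(n_total) - 1L
  truths <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- presets[[groups[i]]]
    p$seed <- NULL  # inherit the experiment-level stream
    truths[[i]] <- simulate_trajectory(p, geom, sectors[i], n_frames)
  }
  metadata <- data.frame(
    fly_id = sprintf("fly%02d", sectors), sector = sectors,
    group = groups, start_clock = start_clock, occupied = TRUE,
    stringsAsFactors = FALSE)
  exp <- structure(list(truths = truths, metadata = metadata, geom = geom,
                        presets = presets, n_frames = n_frames, seed = seed),
                   class = "synthetic_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(ground_truth_table(exp),
              file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    write_geometry_config(geom, file.path(out_dir, "geometry.yaml"))
    if (render) {
      rp <- presets[[1]]
      exp$frames <- render_frames(truths, geom, rp,
                                  out_dir = file.path(out_dir, "frames"))$frames
    }
  } else if (render) {
    exp$rendered <- render_frames(truths, geom, presets[[1]])
  }
  exp
}

#' Convert a ground truth into the trajectory a perfect tracker would emit
#'
#' Dropout frames become invalid; all other frames carry the true position.
#' Useful for testing analytics independently of the tracker.
#'
#' @param truth a `ground_truth` from [simulate_trajectory()].
#' @param fly_id,group,start_clock trajectory metadata.
#' @return a `fly_trajectory`.
#' @export
truth_to_trajectory <- function(truth, fly_id = "truth", group = "unknown",
                                start_clock = NA) {
  x <- truth$x; y <- truth$y
  x[truth$dropout] <- NA; y[truth$dropout] <- NA
  trajectory(x, y, valid = !truth$dropout, fly_id = fly_id,
             sector_id = truth$sector_id, group = group,
             start_clock = start_clock, dt = truth$dt)
}

#' Long-format ground-truth table of a synthetic experiment
#' @param exp a `synthetic_experiment`.
#' @return data.frame: fly_id, sector, group, frame, x_px, y_px, state, dropout.
#' @export
ground_truth_table <- function(exp) {
  do.call(rbind, lapply(seq_along(exp$truths), function(i) {
    tr <- exp$truths[[i]]
    data.frame(fly_id = exp$metadata$fly_id[i], sector = tr$sector_id,
               group = exp$metadata$group[i],
               frame = seq_along(tr$x), x_px = tr$x, y_px = tr$y,
               state = tr$state, dropout = tr$dropout,
               stringsAsFactors = FALSE)
  }))
}
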