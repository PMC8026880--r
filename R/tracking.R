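# Tracking: temporal-median background, per-sector blob detection, and
# identity-by-sector linking. The walled arena guarantees one animal per
# sector, so no frame-to-frame assignment problem exists; a trajectory is
# the time series of the best blob in its sector.

#' Parse / format wall-clock times of day
#'
#' @param x "HH:MM" or "HH:MM:SS" string(s), or numeric seconds since
#'   midnight (returned unchanged).
#' @return seconds since midnight.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% 86400)
  vapply(as.character(x), function(s) {
    parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(parts) < 2 || length(parts) > 3 || anyNA(parts))
      stop("cannot parse clock time: ", s)
    sum(parts * c(3600, 60, 1)[seq_along(parts)]) %% 86400
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname parse_clock
#' @param sec seconds since midnight.
#' @export
format_clock <- function(sec) {
  sec <- round(sec %% 86400)
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

#' Construct a single-fly trajectory
#'
#' @param x,y pixel coordinates per frame (`NA` where invalid).
#' @param valid logical per frame; `valid[i]` FALSE means no detection.
#' @param fly_id identifier.
#' @param sector_id 0-based sector.
#' @param group "pre-fed", "pre-starved" or "unknown".
#' @param start_clock recording start, "HH:MM" or seconds since midnight.
#' @param dt frame interval, s.
#' @return a `fly_trajectory`.
#' @export
trajectory <- function(x, y, valid = !is.na(x), fly_id = "fly00",
                       sector_id = 0L, group = "unknown",
                       start_clock = NA, dt = 1) {
  n <- length(x)
  if (length(y) != n || length(valid) != n)
    stop("x, y and valid must have equal length")
  if (!group %in% c("pre-fed", "pre-starved", "unknown"))
    stop("group must be pre-fed, pre-starved or unknown")
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  if (anyNA(x[valid]) || anyNA(y[valid]))
    stop("valid frames must have defined positions")
  structure(list(fly_id = fly_id, sector_id = as.integer(sector_id),
                 group = group,
                 start_clock = if (is.na(start_clock[1])) NA_real_
                               else parse_clock(start_clock),
                 dt = dt, x = x, y = y, valid = as.logical(valid)),
            class = "fly_trajectory")
}

#' @export
print.fly_trajectory <- function(x, ...) {
  cat(sprintf("<fly_trajectory> %s sector %d group %s: %d frames, %.1f%% valid\n",
              x$fly_id, x$sector_id, x$group, length(x$x),
              100 * mean(x$valid)))
  invisible(x)
}

n_frames <- function(traj) length(traj$x)

# ---- frame sources ---------------------------------------------------------

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3) img <- rowMeans(img, dims = 2)
  img
}

# normalise a frames argument (directory, file vector, or list of matrices)
# to list(n, get = function(i) matrix)
frame_source <- function(frames) {
  if (is.character(frames) && length(frames) == 1 && dir.exists(frames)) {
    files <- sort(list.files(frames, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF frames in ", frames)
    frames <- files
  }
  if (is.character(frames)) {
    fl <- frames
    return(list(n = length(fl), get = function(i) read_frame_file(fl[i])))
  }
  if (is.list(frames) && all(vapply(frames, is.matrix, logical(1))))
    return(list(n = length(frames), get = function(i) frames[[i]]))
  stop("frames must be a directory, file paths, or a list of matrices")
}

# ---- background ------------------------------------------------------------

# exact row-wise median of an n x k matrix by a partial selection network
# (k is small: the background sample size)
row_medians <- function(M) {
  k <- ncol(M)
  m <- (k + 1L) %/% 2L
  for (i in seq_len(if (k %% 2 == 1) m else m + 1L)) {
    for (j in seq(i + 1L, length.out = k - i)) {
      lo <- pmin(M[, i], M[, j])
      M[, j] <- pmax(M[, i], M[, j])
      M[, i] <- lo
    }
  }
  if (k %% 2 == 1) M[, m] else (M[, m] + M[, m + 1L]) / 2
}

#' Estimate the static background by a per-pixel temporal median
#'
#' @param frames a directory of numbered PNG/TIFF images, a character vector
#'   of files, or a list of matrices; at least 25 sampled frames are
#'   required for a robust median.
#' @param n_sample how many frames to sample, spread evenly across the
#'   sequence (default 51).
#' @return background image matrix.
#' @export
estimate_background <- function(frames, n_sample = 51) {
  src <- frame_source(frames)
  idx <- unique(round(seq(1, src$n, length.out = min(n_sample, src$n))))
  if (length(idx) < 25)
    stop("need at least 25 sampled frames, got ", length(idx))
  first <- src$get(idx[1])
  M <- matrix(0, length(first), length(idx))
  M[, 1] <- first
  for (i in seq_along(idx)[-1]) M[, i] <- src$get(idx[i])
  matrix(row_medians(M), nrow(first), ncol(first))
}

# ---- segmentation ----------------------------------------------------------

# 8-connectivity component labels for foreground pixels given by linear
# (column-major) indices; returns an integer membership vector along idx
label_components8 <- function(idx, nr, nc) {
  if (length(idx) == 0) return(integer(0))
  pos <- seq_along(idx)
  lut <- integer(nr * nc)          # 0 = background, else position in idx
  lut[idx] <- pos
  i <- ((idx - 1L) %% nr) + 1L
  edges <- NULL
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))  # S, E, SE, NE
  for (o in offs) {
    ok <- rep(TRUE, length(idx))
    if (o[1] == 1L)  ok <- ok & (i < nr)
    if (o[1] == -1L) ok <- ok & (i > 1L)
    nb <- idx + o[1] + o[2] * nr
    ok <- ok & nb >= 1L & nb <= nr * nc
    nbpos <- integer(length(idx)); nbpos[ok] <- lut[nb[ok]]
    hit <- ok & nbpos > 0L
    if (any(hit)) edges <- rbind(edges, cbind(pos[hit], nbpos[hit]))
  }
  if (is.null(edges)) return(pos)  # all isolated pixels
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}

default_area_bounds <- function(geom) {
  # plausible fly body: disc of 1-4 mm diameter
  c(min = floor(pi * (0.5 / geom$pixel_scale)^2),
    max = ceiling(pi * (2.0 / geom$pixel_scale)^2))
}

#' Detect at most one blob per sector in a single frame
#'
#' Absolute difference from the background is thresholded, 8-connected
#' components are found within the sector regions, components outside the
#' area bounds are discarded, and each sector keeps its largest surviving
#' component as one detection with an intensity-weighted centroid. Equal-area
#' ties go to the component nearer the previous valid position, else the
#' lowest label.
#'
#' @param frame,background image matrices of identical size.
#' @param geom an `arena_geometry`.
#' @param min_area,max_area component area bounds in px^2; defaults span a
#'   1-4 mm body diameter at the geometry's calibration.
#' @param threshold absolute-difference threshold in \[0, 1\] grayscale; if
#'   NULL, `max(5 * MAD(diff), 8/255)` estimated from the difference image.
#' @param prev optional list mapping sector id (as character) to the previous
#'   valid position, used only for tie-breaking.
#' @param frame_index stored in the output.
#' @return data.frame: frame, sector, x, y, area (0 rows if nothing found).
#' @export
segment_frame <- function(frame, background, geom,
                          min_area = NULL, max_area = NULL,
                          threshold = NULL, prev = NULL, frame_index = NA) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background sizes differ")
  bounds <- default_area_bounds(geom)
  if (is.null(min_area)) min_area <- bounds["min"]
  if (is.null(max_area)) max_area <- bounds["max"]
  d <- abs(frame - background)
  if (is.null(threshold)) {
    stp <- max(1L, floor(length(d) / 50000))
    threshold <- max(5 * stats::mad(d[seq(1, length(d), by = stp)]), 8 / 255)
  }
  smask <- sector_mask(geom)
  fg <- which(d > threshold & smask > 0L)
  empty <- data.frame(frame = integer(0), sector = integer(0),
                      x = numeric(0), y = numeric(0), area = numeric(0))
  if (length(fg) == 0) return(empty)
  memb <- label_components8(fg, nrow(frame), ncol(frame))
  area <- tabulate(memb)
  keep_comp <- which(area >= min_area & area <= max_area)
  if (length(keep_comp) == 0) return(empty)
  rows <- lapply(split(seq_along(fg), memb)[as.character(keep_comp)], function(px) {
    id <- fg[px]
    w <- d[id]
    yy <- ((id - 1) %% nrow(frame)) + 1
    xx <- ((id - 1) %/% nrow(frame)) + 1
    sec <- smask[id]
    sec <- as.integer(names(which.max(table(sec)))) - 1L
    data.frame(sector = sec, x = sum(xx * w) / sum(w),
               y = sum(yy * w) / sum(w), area = length(px))
  })
  det <- do.call(rbind, rows)
  det$label <- keep_comp
  # one detection per sector: largest area, ties to nearest previous position
  out <- do.call(rbind, lapply(split(det, det$sector), function(ds) {
    best <- ds[ds$area == max(ds$area), , drop = FALSE]
    if (nrow(best) > 1) {
      pv <- prev[[as.character(best$sector[1])]]
      if (!is.null(pv)) {
        dist2 <- (best$x - pv[1])^2 + (best$y - pv[2])^2
        best <- best[which.min(dist2), , drop = FALSE]
      } else best <- best[which.min(best$label), , drop = FALSE]
    }
    best
  }))
  data.frame(frame = frame_index, sector = out$sector,
             x = out$x, y = out$y, area = out$area, row.names = NULL)
}

#' Link per-frame detections into one trajectory per sector
#'
#' Identity is by sector: the walled arena admits one animal per sector, so
#' every detection in a sector belongs to the same individual. Frames with
#' no detection are marked invalid (no interpolation).
#'
#' @param detections data.frame from [segment_frame()] rows over all frames.
#' @param geom an `arena_geometry`.
#' @param total_frames frame count of the recording.
#' @param metadata optional data.frame with columns `sector`, `group`,
#'   `start_clock` and `occupied`; sectors flagged occupied always yield a
#'   trajectory (possibly all-invalid), detections in sectors declared empty
#'   raise a warning and are kept with group "unknown".
#' @param dt frame interval, s.
#' @return list of `fly_trajectory`.
#' @export
link_trajectories <- function(detections, geom, total_frames,
                              metadata = NULL, dt = 1) {
  det_secs <- sort(unique(detections$sector))
  meta_secs <- if (!is.null(metadata)) metadata$sector[metadata$occupied] else integer(0)
  sectors <- sort(union(det_secs, meta_secs))
  lapply(sectors, function(s) {
    ds <- detections[detections$sector == s, , drop = FALSE]
    group <- "unknown"; start_clock <- NA; fly_id <- sprintf("fly%02d", s)
    if (!is.null(metadata)) {
      row <- metadata[metadata$sector == s, , drop = FALSE]
      if (nrow(row) == 1 && isTRUE(row$occupied)) {
        group <- row$group; start_clock <- row$start_clock
        if (!is.null(row$fly_id)) fly_id <- row$fly_id
      } else if (nrow(ds) > 0) {
        warning("detections in sector ", s,
                " declared empty in metadata; emitting with group=unknown")
      }
    }
    x <- rep(NA_real_, total_frames); y <- rep(NA_real_, total_frames)
    ok <- ds$frame >= 1 & ds$frame <= total_frames
    x[ds$frame[ok]] <- ds$x[ok]; y[ds$frame[ok]] <- ds$y[ok]
    trajectory(x, y, valid = !is.na(x), fly_id = fly_id, sector_id = s,
               group = group, start_clock = start_clock, dt = dt)
  })
}

#' Track a full recording: background, per-frame segmentation, linking
#'
#' @param frames directory, file vector, or list of matrices (time order).
#' @param geom an `arena_geometry`.
#' @param metadata optional sector metadata (see [link_trajectories()]).
#' @param n_background_sample frames sampled for the median background.
#' @param min_area,max_area,threshold passed to [segment_frame()]; the
#'   automatic threshold is estimated once, on the first frame, and reused so
#'   the whole run shares one set of constants.
#' @param dt frame interval, s.
#' @param progress print a line every `progress` frames (0 = silent).
#' @return list: `trajectories`, `detections`, `background`, `threshold`.
#' @export
track_frames <- function(frames, geom, metadata = NULL,
                         n_background_sample = 51,
                         min_area = NULL, max_area = NULL, threshold = NULL,
                         dt = 1, progress = 0) {
  src <- frame_source(frames)
  background <- estimate_background(frames, n_background_sample)
  prev <- list()
  dets <- vector("list", src$n)
  for (t in seq_len(src$n)) {
    fr <- src$get(t)
    if (is.null(threshold)) {   # freeze the auto threshold on first frame
      d <- abs(fr - background)
      stp <- max(1L, floor(length(d) / 50000))
      threshold <- max(5 * stats::mad(d[seq(1, length(d), by = stp)]), 8 / 255)
    }
    det <- segment_frame(fr, background, geom, min_area, max_area,
                         threshold, prev, frame_index = t)
    if (nrow(det) > 0)
      for (i in seq_len(nrow(det)))
        prev[[as.character(det$sector[i])]] <- c(det$x[i], det$y[i])
    dets[[t]] <- det
    if (progress > 0 && t %% progress == 0)
      message("tracked frame ", t, "/", src$n)
  }
  detections <- do.call(rbind, dets)
  list(trajectories = link_trajectories(detections, geom, src$n, metadata, dt),
       detections = detections, background = background,
       threshold = threshold)
}
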