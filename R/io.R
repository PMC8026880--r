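# Trajectory CSV round-trip and the experiment manifest. The CSV schema is
# the pipeline's interchange format:
#   frame, time_s, clock_time, fly_id, sector, x_px, y_px, valid
# (one row per fly per frame; an optional `group` column is preserved).

trajectory_csv_columns <- c("frame", "time_s", "clock_time", "fly_id",
                            "sector", "x_px", "y_px", "valid")

#' Write trajectories to the interchange CSV
#'
#' @param trajs a `fly_trajectory` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajs, path) {
  if (inherits(trajs, "fly_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr) {
    n <- n_frames(tr)
    t_s <- (seq_len(n) - 1) * tr$dt
    data.frame(frame = seq_len(n), time_s = t_s,
               clock_time = if (is.na(tr$start_clock)) ""
                            else format_clock(tr$start_clock + t_s),
               fly_id = tr$fly_id, sector = tr$sector_id,
               x_px = tr$x, y_px = tr$y,
               valid = ifelse(tr$valid, "true", "false"),
               group = tr$group, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

normalise_valid <- function(v) {
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes")] <- TRUE
  out[s %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out))
    stop("schema error: 'valid' contains values other than 0/1/true/false: ",
         paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Read trajectories from the interchange CSV
#'
#' The reader validates the schema (all required columns, per-fly frame
#' numbers strictly increasing and contiguous from 1) and normalises the
#' `valid` column from any of 0/1, true/false spellings.
#'
#' @param path CSV file written by [write_trajectory_csv()] (or compatible).
#' @return list of `fly_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = list(valid = "character"))
  missing <- setdiff(trajectory_csv_columns, names(df))
  if (length(missing) > 0)
    stop("schema error: missing columns: ", paste(missing, collapse = ", "))
  df$valid <- normalise_valid(df$valid)
  lapply(split(df, df$fly_id), function(d) {
    if (!identical(as.integer(d$frame), seq_len(nrow(d))))
      stop("schema error: frames of ", d$fly_id[1],
           " are not contiguous and increasing from 1")
    dt <- if (nrow(d) > 1) d$time_s[2] - d$time_s[1] else 1
    start_clock <- if (nzchar(d$clock_time[1] %||% ""))
      parse_clock(d$clock_time[1]) else NA
    trajectory(d$x_px, d$y_px, valid = d$valid, fly_id = d$fly_id[1],
               sector_id = d$sector[1],
               group = if ("group" %in% names(d)) d$group[1] else "unknown",
               start_clock = start_clock, dt = dt)
  })
}

#' Read an experiment manifest
#'
#' A manifest is a YAML file (or an equivalent named list) tying a recording
#' to its configuration:
#' `frames` (image directory), `geometry` (geometry YAML path),
#' `metadata` (CSV with fly_id, sector, group, start_clock, occupied),
#' `out_dir`, and optional analysis settings (see [run_pipeline()]).
#'
#' @param manifest path to a YAML manifest, or a named list.
#' @return validated manifest list with `geom` and `metadata` loaded.
#' @export
read_manifest <- function(manifest) {
  m <- if (is.character(manifest)) yaml::read_yaml(manifest) else manifest
  base <- if (is.character(manifest)) dirname(manifest) else "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (key in c("frames", "geometry", "metadata")) {
    if (is.null(m[[key]])) stop("manifest missing required field: ", key)
  }
  if (is.character(m$frames)) {
    m$frames <- resolve(m$frames)
    if (!dir.exists(m$frames)) stop("frames directory not found: ", m$frames)
  }
  m$geom <- if (inherits(m$geometry, "arena_geometry")) m$geometry
            else read_geometry_config(resolve(m$geometry))
  if (is.character(m$metadata)) {
    p <- resolve(m$metadata)
    if (!file.exists(p)) stop("metadata file not found: ", p)
    m$metadata <- read.csv(p, stringsAsFactors = FALSE)
  }
  need <- c("sector", "group", "occupied")
  missing <- setdiff(need, names(m$metadata))
  if (length(missing) > 0)
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(m$metadata$group), c("pre-fed", "pre-starved", "unknown"))
  if (length(bad) > 0)
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (is.null(m$out_dir)) m$out_dir <- "output"
  if (!startsWith(m$out_dir, "/")) m$out_dir <- file.path(base, m$out_dir)
  m
}
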