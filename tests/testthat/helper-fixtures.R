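# Shared fixtures. Most tests use a coarse calibration (85 mm dish over a
# small image) so rasterisation, rendering and tracking stay fast; the
# default full-resolution geometry is exercised where the printed arena
# constants themselves are under test.

small_geom <- function(px = 256, ...) {
  build_default_geometry(list(pixel_scale = 85 / px, ...))
}

# memoised default geometry (mask rasterisation at 1700 px is the slow part)
default_geom <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- build_default_geometry()
    g
  }
})

# trajectory with explicit positions (px), valid everywhere unless NA
make_traj <- function(x, y, dt = 1, start_clock = NA, group = "unknown",
                      sector_id = 0L) {
  trajectory(x, y, valid = !is.na(x), sector_id = sector_id, group = group,
             start_clock = start_clock, dt = dt)
}

# displacement series straight from numbers (mm), for metric unit tests
disp_from_mm <- function(mm, pixel_scale = 0.05, dt = 1) {
  defined <- !is.na(mm)
  structure(list(px = mm / pixel_scale, mm = mm, defined = defined, dt = dt),
            class = "displacement_series")
}

flags_from <- function(moving, defined = rep(TRUE, length(moving)), dt = 1) {
  structure(list(moving = moving & defined, defined = defined, dt = dt),
            class = "motion_flags")
}
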