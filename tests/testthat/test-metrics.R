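g05 <- structure(list(pixel_scale = 0.05), class = "arena_geometry")

test_that("displacements convert px to mm and never cross gaps", {
  tr <- make_traj(c(0, 3, 3, 3), c(0, 4, 4, 4))
  d <- displacement_series(tr, g05)
  expect_equal(d$mm, c(0.25, 0, 0))           # 5 px at 0.05 mm/px
  expect_true(all(d$mm >= 0))
  st <- make_traj(rep(7, 5), rep(9, 5))
  expect_equal(displacement_series(st, g05)$mm, rep(0, 4))
  # invalid middle frame undefines both adjacent pairs
  gap <- make_traj(c(1, NA, 3), c(1, NA, 3))
  dg <- displacement_series(gap, g05)
  expect_equal(dg$defined, c(FALSE, FALSE))
  expect_true(all(is.na(dg$mm)))
})

test_that("stationarity floor is 2 px, inclusive on the moving side", {
  d <- structure(list(px = c(1.9, 2.0, 0, 3, 0, 5),
                      mm = c(1.9, 2.0, 0, 3, 0, 5) * 0.05,
                      defined = rep(TRUE, 6), dt = 1),
                 class = "displacement_series")
  f <- motion_flags(d)
  expect_equal(f$moving, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_true(all(f$defined[f$moving]))       # moving implies defined
  expect_error(motion_flags(d, 0), "> 0")
})

test_that("binned activity is the moving fraction over defined pairs", {
  f <- flags_from(rep(TRUE, 600))
  a <- activity_binned(f, 300)
  expect_equal(a$value, c(1, 1))
  half <- flags_from(rep(c(TRUE, FALSE), 150))
  expect_equal(activity_binned(half, 300)$value, 0.5)
  # trailing partial bin is dropped; undefined-only bin is NA
  f2 <- flags_from(rep(TRUE, 700), defined = c(rep(TRUE, 300), rep(FALSE, 300),
                                               rep(TRUE, 100)))
  a2 <- activity_binned(f2, 300)
  expect_equal(nrow(a2), 2)
  expect_equal(a2$value, c(1, NA_real_))
})

test_that("stops are maximal runs, split at gaps, floored at 2 s", {
  # 10 stationary pairs in a row: one 10 s stop
  f <- flags_from(c(rep(TRUE, 3), rep(FALSE, 10), rep(TRUE, 3)))
  tr <- make_traj(seq_len(17), rep(1, 17))
  s <- find_stops(f, tr)
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_s, 10)
  expect_equal(s$start_frame, 4)
  expect_equal(s$x, mean(4:14))
  expect_equal(nrow(find_stops(flags_from(rep(TRUE, 20)), make_traj(1:20, 1:20))), 0)
  # 1 s run is below the retention floor
  f1 <- flags_from(c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(find_stops(f1, make_traj(1:5, 1:5))), 0)
  # an undefined pair splits a would-be long run into two short ones
  fsplit <- flags_from(rep(FALSE, 9), defined = c(rep(TRUE, 4), FALSE, rep(TRUE, 4)))
  ssplit <- find_stops(fsplit, make_traj(rep(1, 10), rep(1, 10)))
  expect_equal(ssplit$duration_s, c(4, 4))
})

test_that("log2 stop bins follow the 2-3 s, 4-7 s, 8-15 s pattern", {
  stops <- data.frame(start_frame = 1:5, duration_s = c(2, 3, 4, 7, 8),
                      x = 0, y = 0)
  h <- stop_histogram_log2(stops)
  expect_equal(h$count[h$k == 1], 2)     # 2 s and 3 s
  expect_equal(h$count[h$k == 2], 2)     # 4 s and 7 s
  expect_equal(h$count[h$k == 3], 1)     # 8 s in [8, 15]
  expect_equal(h$duration_range[1:2], c("2-3 s", "4-7 s"))
  # window filtering by stop start (elapsed seconds)
  hw <- stop_histogram_log2(stops, time_window = c(0, 2))
  expect_equal(sum(hw$count), 2)
})

test_that("displacement classes count short and long walks inclusively", {
  h <- displacement_histogram(disp_from_mm(rep(1, 10)))
  expect_equal(h$short, 1)
  expect_equal(h$long, 0)
  h2 <- displacement_histogram(disp_from_mm(c(1, 1, 6, 6)))
  expect_equal(h2$short, 0.5)
  expect_equal(h2$long, 0.5)
  expect_equal(sum(h2$prob), 1)
  # class bounds are inclusive at both ends
  h3 <- displacement_histogram(disp_from_mm(c(0.1, 2, 5, 10)))
  expect_equal(h3$short, 0.5)
  expect_equal(h3$long, 0.5)
  # sub-floor jitter contributes to neither class (coarse calibration makes
  # 0.05 mm pairs "moving": 2 px floor with 0.02 mm/px = 0.04 mm)
  d <- disp_from_mm(c(0.05, 1), pixel_scale = 0.02)
  h4 <- displacement_histogram(d)
  expect_equal(h4$n, 2)                   # both count as moving...
  expect_equal(h4$short, 0.5)             # ...but 0.05 mm is in no class
  expect_equal(h4$long, 0)
  # no moving pairs: undefined distribution
  h5 <- displacement_histogram(disp_from_mm(numeric(0)))
  expect_true(is.na(h5$short))
})

test_that("histograms match a naive single-pass loop", {
  set.seed(91)
  for (rep in 1:5) {
    mm <- round(runif(40, 0, 16), 2)
    h <- displacement_histogram(disp_from_mm(mm), bin_width_mm = 0.5, max_mm = 15)
    mv <- mm[mm / 0.05 >= 2]        # the moving set: at or above the 2 px floor
    naive <- numeric(30)
    for (v in mv) {
      b <- min(max(ceiling(v / 0.5), 1), 30)
      naive[b] <- naive[b] + 1
    }
    expect_equal(h$prob, naive / length(mv))
    expect_equal(h$short, sum(mv >= 0.1 & mv <= 2) / length(mv))
    expect_equal(h$long, sum(mv >= 5 & mv <= 10) / length(mv))
  }
})

test_that("occupancy fraction tracks ROI residency per bin", {
  geom <- small_geom()
  roi <- geom$patch_rois[[1]]
  n <- 600
  at_patch <- make_traj(rep(roi$center[1], n), rep(roi$center[2], n))
  occ <- occupancy_fraction(at_patch, geom, roi, 300)
  expect_equal(occ$value, c(1, 1))
  ctr <- flyarena:::sector_centroid(geom, 4)
  away <- make_traj(rep(ctr[1], n), rep(ctr[2], n), sector_id = 4L)
  expect_equal(occupancy_fraction(away, geom, roi, 300)$value, c(0, 0))
})

test_that("uniform positions occupy the patch at the area ratio", {
  geom <- small_geom(400)
  sr <- geom$sector_regions[[1]]
  set.seed(101)
  n <- 20000
  r <- sqrt(runif(n, sr$r_in_px^2, sr$r_out_px^2))
  th <- runif(n, sr$theta0, sr$theta1)
  x <- geom$center[1] + r * cos(th); y <- geom$center[2] + r * sin(th)
  tr <- make_traj(x, y)
  occ <- mean(point_in_roi(geom, geom$patch_rois[[1]], cbind(x, y)))
  p0 <- 0.2 / 5.5
  expect_lt(abs(occ - p0), 4 * sqrt(p0 * (1 - p0) / n))
})

test_that("clock alignment co-bins flies started at different times", {
  # start 12:00: a pair at 7 h elapsed falls in the 19:00 bin
  f <- flags_from(rep(TRUE, 8 * 3600))
  a <- activity_binned(f, 1800, align = "clock", start_clock = "12:00")
  expect_true((19 * 3600) %in% a$bin_start)
  expect_equal(min(a$bin_start), 12 * 3600)
  # align_series maps elapsed bins onto the same clock grid
  ser <- activity_binned(f, 1800)
  al <- align_series(ser, "12:00", "clock", 1800)
  expect_setequal(al$bin_start, a$bin_start)
  # two flies started 1 h apart put their 19:00 values in the same bin
  f2 <- flags_from(rep(TRUE, 8 * 3600))
  a2 <- activity_binned(f2, 1800, align = "clock", start_clock = "13:00")
  expect_true((19 * 3600) %in% intersect(a$bin_start, a2$bin_start))
  expect_error(activity_binned(f, 1800, align = "clock"), "start_clock")
  expect_identical(align_series(ser, mode = "start"), ser)
})

test_that("moving, stopped and undefined time partition the recording", {
  set.seed(111)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    defined <- runif(n) > 0.2
    moving <- defined & runif(n) > 0.5
    f <- flags_from(moving, defined)
    b <- time_budget(f)
    expect_identical(b$moving_s + b$stopped_s + b$undefined_s, b$total_s)
    # and per bin the moving + stationary fractions sum to one
    a <- activity_binned(f, n)      # one bin spanning everything
    if (!is.na(a$value[1]))
      expect_equal(a$value[1] + (sum(defined & !moving) / sum(defined)), 1)
  }
})

test_that("activity and stop law are recovered from simulated ground truth", {
  geom <- small_geom()
  p <- walk_params(p_stop_to_walk = 0.25, p_walk_to_stop = 0.2,
                   speed_log_mean = log(4), seed = 121)
  n <- 20000
  tr <- simulate_trajectory(p, geom, 0, n)
  traj <- truth_to_trajectory(tr)
  flags <- motion_flags(displacement_series(traj, geom))
  # walk-state fraction vs measured moving fraction (a stop->walk frame pair
  # moves, so compare against pairs whose *first* frame is a walk state)
  walk_pairs <- tr$state[-n] == "walk"
  p_hat <- mean(flags$moving)
  p_true <- mean(walk_pairs)
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / n) + 0.01)
  # stop durations: maximal stationary runs follow the geometric law of
  # p_stop_to_walk; conditional on duration >= 2 the excess is geometric
  stops <- find_stops(flags, traj)
  excess <- stops$duration_s - 2
  p_geo <- p$p_stop_to_walk
  expect_equal(mean(excess), (1 - p_geo) / p_geo,
               tolerance = 5 / sqrt(nrow(stops)))
  # distributional check against the geometric pmf
  kmax <- 6
  obs <- tabulate(pmin(excess, kmax) + 1, kmax + 1)
  pexp <- c(dgeom(0:(kmax - 1), p_geo), 1 - pgeom(kmax - 1, p_geo))
  cs <- suppressWarnings(chisq.test(obs, p = pexp))
  expect_gt(cs$p.value, 0.001)
})
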