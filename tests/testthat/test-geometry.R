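test_that("default arena matches the printed constants", {
  geom <- default_geom()
  expect_equal(geom$n_sectors, 8L)
  areas <- vapply(geom$sector_regions, function(s) region_area(geom, s),
                  numeric(1))
  expect_true(all(abs(areas - 5.5) / 5.5 < 0.02))
  expect_length(geom$patch_rois, 8)
  parea <- vapply(geom$patch_rois, function(r) region_area(geom, r),
                  numeric(1))
  expect_true(all(abs(parea - 0.2) / 0.2 < 0.02))
  # closed-form patch radius: circle of 0.2 cm^2
  r_mm <- geom$patch_rois[[1]]$radius_px * geom$pixel_scale
  expect_equal(r_mm, sqrt(20 / pi), tolerance = 1e-6)
  expect_equal(px_to_mm(geom, 2), 0.1)
})

test_that("degenerate and invalid configurations are handled", {
  g1 <- build_default_geometry(list(n_sectors = 1, patch_area_cm2 = 0,
                                    pixel_scale = 85 / 256))
  expect_equal(g1$n_sectors, 1L)
  expect_length(g1$patch_rois, 0)
  expect_error(build_default_geometry(list(pixel_scale = -1)), "pixel_scale")
  expect_error(build_default_geometry(list(pixel_scale = 0)), "pixel_scale")
  expect_error(build_default_geometry(list(image_width = -5)), "dimensions|unattainable")
  expect_error(build_default_geometry(list(sector_area_cm2 = 50)),
               "unattainable")
  # dish does not fit: small image at fine calibration
  expect_error(build_default_geometry(list(image_width = 200, image_height = 200)),
               "unattainable")
  expect_error(build_default_geometry(list(bogus_key = 1)), "unknown")
})

test_that("px_to_mm converts linearly and rejects negative distances", {
  geom <- small_geom()
  g05 <- list(pixel_scale = 0.05)
  class(g05) <- "arena_geometry"
  expect_equal(px_to_mm(g05, 0), 0)
  expect_equal(px_to_mm(g05, 40), 2.0)
  expect_error(px_to_mm(geom, -1), "non-negative")
})

test_that("assign_sector agrees with rasterised mask lookup", {
  geom <- small_geom(256)
  m <- sector_mask(geom)
  set.seed(7)
  # random points at pixel centres, mix of inside/outside
  j <- sample(ncol(m), 1000, replace = TRUE)
  i <- sample(nrow(m), 1000, replace = TRUE)
  got <- assign_sector(geom, cbind(j, i))
  ref <- ifelse(m[cbind(i, j)] > 0, m[cbind(i, j)] - 1L, NA_integer_)
  expect_identical(got, as.integer(ref))
  # wedge centroid lands in its own sector; corner is outside the dish
  for (k in c(0L, 3L, 7L))
    expect_identical(assign_sector(geom, flyarena:::sector_centroid(geom, k)), k)
  expect_true(is.na(assign_sector(geom, c(1, 1))))
  expect_error(assign_sector(geom, c(-5, 10)), "outside image")
})

test_that("point_in_roi is boundary-inclusive", {
  geom <- small_geom()
  roi <- geom$patch_rois[[1]]
  expect_true(point_in_roi(geom, roi, roi$center))
  expect_true(point_in_roi(geom, roi, roi$center + c(roi$radius_px, 0)))
  expect_false(point_in_roi(geom, roi, roi$center + c(roi$radius_px + 1, 0)))
})

test_that("ROI membership matches rasterised mask lookup", {
  geom <- small_geom(256)
  roi <- geom$patch_rois[[2]]
  set.seed(11)
  pts <- cbind(runif(500, roi$center[1] - 15, roi$center[1] + 15),
               runif(500, roi$center[2] - 15, roi$center[2] + 15))
  got <- point_in_roi(geom, roi, pts)
  ref <- (pts[, 1] - roi$center[1])^2 + (pts[, 2] - roi$center[2])^2 <=
    roi$radius_px^2 + 1e-9
  expect_identical(got, ref)
})

test_that("region_area: sectors are disjoint, fit in the dish, scale-invariant", {
  geom <- small_geom(256)
  m <- sector_mask(geom)
  areas <- vapply(geom$sector_regions, function(s) region_area(geom, s),
                  numeric(1))
  dish_area_cm2 <- pi * geom$dish_radius^2 / 100
  expect_lt(sum(areas), dish_area_cm2 + 1e-9)
  # a single-valued label mask is pairwise-disjoint by construction; check
  # every labelled pixel maps back to exactly one sector
  expect_true(all(m %in% 0:8))
  # resolution invariance at fixed mm dimensions (within rasterisation error)
  a256 <- region_area(small_geom(256), small_geom(256)$sector_regions[[1]])
  a400 <- region_area(small_geom(400), small_geom(400)$sector_regions[[1]])
  expect_lt(abs(a256 - a400) / a400, 0.02)
  # one-pixel region at the default calibration
  tiny <- structure(list(label = "t", sector_id = 0L,
                         center = c(100, 100), radius_px = 0.4),
                    class = "arena_roi")
  expect_equal(region_area(default_geom(), tiny), 2.5e-5)
  expect_error(region_area(geom, structure(list(center = c(-50, -50), radius_px = 0.1),
                                           class = "arena_roi")),
               "empty")
})

test_that("patch ROIs lie entirely within their sectors", {
  geom <- small_geom(400)
  m <- sector_mask(geom)
  for (roi in geom$patch_rois) {
    # every rasterised ROI pixel carries its sector's label
    r <- roi$radius_px
    jr <- floor(roi$center[1] - r):ceiling(roi$center[1] + r)
    ir <- floor(roi$center[2] - r):ceiling(roi$center[2] + r)
    xg <- matrix(jr, length(ir), length(jr), byrow = TRUE)
    yg <- matrix(ir, length(ir), length(jr))
    inside <- (xg - roi$center[1])^2 + (yg - roi$center[2])^2 <= r^2
    labs <- m[cbind(yg[inside], xg[inside])]
    expect_true(all(labs == roi$sector_id + 1L))
  }
  # virtual patches mirror the physical ones in size and placement
  expect_equal(length(geom$virtual_patch_rois), length(geom$patch_rois))
  expect_equal(geom$virtual_patch_rois[[3]]$center, geom$patch_rois[[3]]$center)
  expect_equal(geom$virtual_patch_rois[[3]]$radius_px,
               geom$patch_rois[[3]]$radius_px)
})

test_that("mask-based geometry answers sector queries by lookup", {
  mask <- matrix(0L, 40, 40)
  mask[5:20, 5:20] <- 1L
  mask[25:35, 25:35] <- 2L
  g <- geometry_from_mask(mask, pixel_scale = 0.5)
  expect_equal(g$n_sectors, 2L)
  expect_identical(assign_sector(g, c(10, 10)), 0L)
  expect_identical(assign_sector(g, c(30, 30)), 1L)
  expect_true(is.na(assign_sector(g, c(2, 2))))
  expect_equal(region_area(g, g$sector_regions[[1]]),
               16 * 16 * 0.25 / 100)
})

test_that("geometry config round-trips through YAML", {
  geom <- small_geom(256)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_geometry_config(geom, f)
  g2 <- read_geometry_config(f)
  expect_equal(g2$pixel_scale, geom$pixel_scale)
  expect_equal(g2$n_sectors, geom$n_sectors)
  expect_equal(g2$sector_regions[[1]]$r_in_px, geom$sector_regions[[1]]$r_in_px,
               tolerance = 1e-6)
  expect_equal(g2$patch_rois[[1]]$radius_px, geom$patch_rois[[1]]$radius_px,
               tolerance = 1e-6)
})
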