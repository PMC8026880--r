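# Coordinate conventions used throughout:
#   origin at the top-left pixel centre, x to the right (matrix column),
#   y downwards (matrix row), 1-based pixel centres; all geometry is kept in
#   continuous pixel coordinates and rasterised only when a mask is needed.

#' Build the default multi-sector arena geometry
#'
#' Models a circular dish partitioned into `n_sectors` walled, equal annular
#' wedges, each holding one animal, with an optional circular food-patch ROI
#' per sector (plus same-sized "virtual" patch ROIs for patch-free assays).
#' The inner wedge radius is solved in closed form so every sector integrates
#' to `sector_area_cm2` at the configured `pixel_scale`.
#'
#' Defaults model an 85 mm dish split into 8 sectors of 5.5 cm^2 with one
#' 0.2 cm^2 patch per sector, imaged so that 2 px correspond to 0.1 mm
#' (`pixel_scale = 0.05` mm/px); the default image side is therefore
#' 1700 px (85 mm / 0.05 mm/px), the smallest square holding the dish at
#' that calibration.
#'
#' @param config named list of overrides. Recognised keys:
#'   `image_width`, `image_height` (px), `pixel_scale` (mm/px),
#'   `dish_diameter_mm`, `n_sectors`, `sector_area_cm2`, `patch_area_cm2`,
#'   `patches` (logical; physical patches present), `center` (length-2 px),
#'   `wall_mm` (rendered wall thickness, cosmetic).
#' @return an object of class `arena_geometry`.
#' @examples
#' geom <- build_default_geometry()
#' region_area(geom, geom$sector_regions[[1]])   # ~5.5 cm^2
#' @export
build_default_geometry <- function(config = list()) {
  defaults <- list(
    pixel_scale = 0.05,          # mm per px: 2 px = 0.1 mm
    dish_diameter_mm = 85,
    n_sectors = 8L,
    sector_area_cm2 = 5.5,
    patch_area_cm2 = 0.2,
    patches = TRUE,
    wall_mm = 0.8,
    image_width = NULL, image_height = NULL, center = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown geometry config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)

  if (!is.numeric(cfg$pixel_scale) || cfg$pixel_scale <= 0)
    stop("pixel_scale must be > 0")
  if (cfg$n_sectors < 1) stop("n_sectors must be >= 1")
  if (cfg$sector_area_cm2 <= 0) stop("sector_area_cm2 must be > 0")

  dish_radius_mm <- cfg$dish_diameter_mm / 2
  # default image: smallest square containing the dish at this calibration
  side <- ceiling(cfg$dish_diameter_mm / cfg$pixel_scale)
  w <- if (is.null(cfg$image_width)) side else as.integer(cfg$image_width)
  h <- if (is.null(cfg$image_height)) side else as.integer(cfg$image_height)
  if (w <= 0 || h <= 0) stop("image dimensions must be positive")
  center <- if (is.null(cfg$center)) c((w + 1) / 2, (h + 1) / 2) else cfg$center

  r_out_mm <- dish_radius_mm
  need_mm2 <- cfg$n_sectors * cfg$sector_area_cm2 * 100
  r_in_sq <- r_out_mm^2 - need_mm2 / pi
  if (r_in_sq < 0)
    stop("sector area unattainable: ", cfg$n_sectors, " x ",
         cfg$sector_area_cm2, " cm^2 exceeds the dish disc")
  r_in_mm <- sqrt(r_in_sq)
  r_out_px <- r_out_mm / cfg$pixel_scale
  if (r_out_px > min(center[1] - 0.5, center[2] - 0.5,
                     w - center[1] + 0.5, h - center[2] + 0.5) + 0.5)
    stop("sector area unattainable: dish of radius ", round(r_out_px),
         " px does not fit in a ", w, "x", h, " image")

  dtheta <- 2 * pi / cfg$n_sectors
  sector_regions <- lapply(seq_len(cfg$n_sectors) - 1L, function(k) {
    structure(list(sector_id = k,
                   theta0 = k * dtheta, theta1 = (k + 1) * dtheta,
                   r_in_px = r_in_mm / cfg$pixel_scale,
                   r_out_px = r_out_px),
              class = "sector_region")
  })

  geom <- structure(list(
    image_width = w, image_height = h, center = center,
    dish_radius = dish_radius_mm, pixel_scale = cfg$pixel_scale,
    n_sectors = as.integer(cfg$n_sectors),
    sector_inner_mm = r_in_mm, sector_outer_mm = r_out_mm,
    wall_mm = cfg$wall_mm,
    sector_regions = sector_regions,
    patch_rois = list(), virtual_patch_rois = list(),
    label_mask = NULL,
    .cache = new.env(parent = emptyenv())
  ), class = "arena_geometry")

  if (cfg$patch_area_cm2 > 0) {
    r_patch_mm <- sqrt(cfg$patch_area_cm2 * 100 / pi)
    rois <- lapply(sector_regions, function(sr) {
      ctr <- sector_centroid(geom, sr$sector_id)
      roi <- structure(list(label = paste0("patch_s", sr$sector_id),
                            sector_id = sr$sector_id,
                            center = ctr,
                            radius_px = r_patch_mm / cfg$pixel_scale),
                       class = "arena_roi")
      if (!circle_in_sector(geom, sr, ctr, roi$radius_px))
        stop("patch ROI does not fit inside sector ", sr$sector_id)
      roi
    })
    virtual <- lapply(rois, function(r) { r$label <- sub("^patch", "vpatch", r$label); r })
    if (isTRUE(cfg$patches)) geom$patch_rois <- rois
    geom$virtual_patch_rois <- virtual
  }
  geom
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("<arena_geometry> %dx%d px, %.4g mm/px, %d sectors (%.3g-%.3g mm radial band), %d patch ROIs\n",
              x$image_width, x$image_height, x$pixel_scale, x$n_sectors,
              x$sector_inner_mm, x$sector_outer_mm, length(x$patch_rois)))
  invisible(x)
}

# area centroid of the annular wedge, in continuous px
sector_centroid <- function(geom, sector_id) {
  sr <- geom$sector_regions[[sector_id + 1L]]
  half <- (sr$theta1 - sr$theta0) / 2
  r1 <- sr$r_in_px; r2 <- sr$r_out_px
  r_c <- (2 / 3) * (r2^3 - r1^3) / (r2^2 - r1^2) * (sin(half) / half)
  th <- (sr$theta0 + sr$theta1) / 2
  geom$center + r_c * c(cos(th), sin(th))
}

circle_in_sector <- function(geom, sr, center, radius_px) {
  d <- center - geom$center
  r <- sqrt(sum(d^2))
  if (r - radius_px < sr$r_in_px || r + radius_px > sr$r_out_px) return(FALSE)
  half <- (sr$theta1 - sr$theta0) / 2
  # angular clearance from the wedge bisector
  th <- (atan2(d[2], d[1])) %% (2 * pi)
  bis <- (sr$theta0 + sr$theta1) / 2
  dth <- abs(((th - bis + pi) %% (2 * pi)) - pi)
  dth + asin(min(1, radius_px / r)) <= half + 1e-12
}

polar_about_center <- function(geom, x, y) {
  dx <- x - geom$center[1]; dy <- y - geom$center[2]
  list(r = sqrt(dx^2 + dy^2), theta = atan2(dy, dx) %% (2 * pi))
}

#' Assign an image point to a sector
#'
#' @param geom an `arena_geometry`.
#' @param p numeric length-2 point `(x, y)` in px, or an n-by-2 matrix.
#' @return integer sector id (0-based) per point, `NA` for points on walls or
#'   outside the dish annulus.
#' @export
assign_sector <- function(geom, p) {
  p <- rbind(p); dimnames(p) <- NULL
  if (any(p[, 1] < 0.5 | p[, 1] > geom$image_width + 0.5 |
          p[, 2] < 0.5 | p[, 2] > geom$image_height + 0.5, na.rm = TRUE))
    stop("point outside image bounds")
  if (!is.null(geom$label_mask)) {
    i <- round(p[, 2]); j <- round(p[, 1])
    v <- geom$label_mask[cbind(i, j)]
    return(ifelse(v > 0, as.integer(v - 1L), NA_integer_))
  }
  pol <- polar_about_center(geom, p[, 1], p[, 2])
  sr1 <- geom$sector_regions[[1]]
  inside <- pol$r >= sr1$r_in_px & pol$r <= sr1$r_out_px
  k <- floor(pol$theta / (2 * pi / geom$n_sectors))
  k[k == geom$n_sectors] <- 0L          # theta == 2*pi wrap
  ifelse(inside, as.integer(k), NA_integer_)
}

#' Test whether a point lies inside a circular ROI (boundary inclusive)
#'
#' @param geom an `arena_geometry` (unused for circle ROIs, kept for a uniform
#'   signature with mask-based regions).
#' @param roi an `arena_roi`.
#' @param p numeric length-2 point (x, y) px, or n-by-2 matrix.
#' @return logical per point.
#' @export
point_in_roi <- function(geom, roi, p) {
  p <- rbind(p); dimnames(p) <- NULL
  d2 <- (p[, 1] - roi$center[1])^2 + (p[, 2] - roi$center[2])^2
  d2 <= roi$radius_px^2 + 1e-9
}

#' Convert a pixel distance to millimetres
#'
#' @param geom an `arena_geometry`.
#' @param d distance(s) in px, non-negative.
#' @return distance(s) in mm (`d * pixel_scale`).
#' @export
px_to_mm <- function(geom, d) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be non-negative")
  d * geom$pixel_scale
}

#' Integer sector label mask for the arena
#'
#' Rasterises the sector partition: 0 = outside any sector (wall, dish
#' centre, outside dish), k+1 = sector k. Cached on the geometry.
#'
#' @param geom an `arena_geometry`.
#' @return integer matrix of dim (image_height, image_width).
#' @export
sector_mask <- function(geom) {
  if (!is.null(geom$label_mask)) return(geom$label_mask)
  if (!is.null(geom$.cache$label_mask)) return(geom$.cache$label_mask)
  w <- geom$image_width; h <- geom$image_height
  dx <- rep(seq_len(w) - geom$center[1], each = h)    # column-major grid
  dy <- rep(seq_len(h) - geom$center[2], times = w)
  r2 <- dx * dx + dy * dy
  sr1 <- geom$sector_regions[[1]]
  inside <- r2 >= sr1$r_in_px^2 & r2 <= sr1$r_out_px^2
  th <- atan2(dy[inside], dx[inside]) %% (2 * pi)
  k <- floor(th / (2 * pi / geom$n_sectors))
  k[k == geom$n_sectors] <- 0
  m <- matrix(0L, h, w)
  m[inside] <- as.integer(k) + 1L
  geom$.cache$label_mask <- m
  m
}

#' Area of a sector region or ROI in cm^2
#'
#' Pixel count of the rasterised region times `pixel_scale^2 / 100`.
#'
#' @param geom an `arena_geometry`.
#' @param region a `sector_region` or `arena_roi` belonging to `geom`.
#' @return area in cm^2.
#' @export
region_area <- function(geom, region) {
  npx <- if (inherits(region, "sector_region")) {
    if (is.null(geom$.cache$sector_px))
      geom$.cache$sector_px <- tabulate(sector_mask(geom), geom$n_sectors)
    geom$.cache$sector_px[region$sector_id + 1L]
  } else if (inherits(region, "arena_roi")) {
    # count pixel centres within the circle (inclusive)
    r <- region$radius_px
    jr <- max(1, floor(region$center[1] - r)):min(geom$image_width, ceiling(region$center[1] + r))
    ir <- max(1, floor(region$center[2] - r)):min(geom$image_height, ceiling(region$center[2] + r))
    xg <- matrix(jr, length(ir), length(jr), byrow = TRUE)
    yg <- matrix(ir, length(ir), length(jr))
    sum((xg - region$center[1])^2 + (yg - region$center[2])^2 <= r^2 + 1e-9)
  } else stop("region must be a sector_region or arena_roi")
  if (npx == 0) stop("empty region")
  npx * geom$pixel_scale^2 / 100
}

#' Build a geometry from a user-supplied sector label mask
#'
#' Escape hatch for arenas whose sector layout is not the default annular
#' wedge partition: supply an integer image (0 = background, k = sector k's
#' pixels, 1-based labels) and a calibration.
#'
#' @param mask integer matrix (rows = image y, cols = image x); values 0..n.
#' @param pixel_scale mm per px.
#' @param patch_rois optional list of `arena_roi`.
#' @return an `arena_geometry` whose sector queries use mask lookup.
#' @export
geometry_from_mask <- function(mask, pixel_scale, patch_rois = list()) {
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  n <- max(mask)
  if (n < 1) stop("mask contains no sector labels")
  regions <- lapply(seq_len(n) - 1L, function(k)
    structure(list(sector_id = k), class = "sector_region"))
  structure(list(
    image_width = ncol(mask), image_height = nrow(mask),
    center = c((ncol(mask) + 1) / 2, (nrow(mask) + 1) / 2),
    dish_radius = NA_real_, pixel_scale = pixel_scale,
    n_sectors = as.integer(n),
    sector_inner_mm = NA_real_, sector_outer_mm = NA_real_,
    wall_mm = 0,
    sector_regions = regions,
    patch_rois = patch_rois, virtual_patch_rois = patch_rois,
    label_mask = mask,
    .cache = new.env(parent = emptyenv())
  ), class = "arena_geometry")
}

#' Serialise a geometry's configuration to a YAML file
#'
#' Only the construction parameters are written; the geometry is rebuilt
#' deterministically with [build_default_geometry()] on read.
#'
#' @param geom an `arena_geometry` built by [build_default_geometry()].
#' @param path output file.
#' @export
write_geometry_config <- function(geom, path) {
  if (!is.null(geom$label_mask))
    stop("mask-based geometries are serialised as the mask image, not YAML")
  cfg <- list(
    image_width = geom$image_width, image_height = geom$image_height,
    pixel_scale = geom$pixel_scale,
    dish_diameter_mm = geom$dish_radius * 2,
    n_sectors = geom$n_sectors,
    sector_area_cm2 = pi * (geom$sector_outer_mm^2 - geom$sector_inner_mm^2) /
      geom$n_sectors / 100,
    patch_area_cm2 = if (length(geom$virtual_patch_rois) > 0)
      pi * (geom$virtual_patch_rois[[1]]$radius_px * geom$pixel_scale)^2 / 100 else 0,
    patches = length(geom$patch_rois) > 0,
    wall_mm = geom$wall_mm
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a geometry configuration written by [write_geometry_config()]
#' @param path YAML file.
#' @return an `arena_geometry`.
#' @export
read_geometry_config <- function(path) {
  build_default_geometry(yaml::read_yaml(path))
}
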