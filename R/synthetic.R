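# Synthetic oblique scenes: in-gamut pink-purple ellipse "flowers" on
# out-of-gamut vegetation-like backgrounds, with the failure-mode
# distractors seen in real riverbank imagery (sunlit stems sharing the
# flower hue, near-white flowers) available on demand.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

hsv_byte_to_rgb <- function(h, s, v) {
  col2rgb(grDevices::hsv(pmin(h, 254.9) / 255, s / 255, v / 255))
}

# pixels of an axis-aligned ellipse spanning w x h px centred at (cx, cy)
# (continuous coordinates, 0-based); strict-interior midpoint rule so the
# rasterised hull is exactly w x h
rasterize_ellipse <- function(cx, cy, w, h, W, H) {
  x0 <- max(0L, floor(cx - w / 2)); x1 <- min(W - 1L, ceiling(cx + w / 2))
  y0 <- max(0L, floor(cy - h / 2)); y1 <- min(H - 1L, ceiling(cy + h / 2))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, times = length(xs)), length(ys))
  inside <- ((gx - cx) / (w / 2))^2 + ((gy - cy) / (h / 2))^2 < 1
  cbind(x = gx[inside], y = gy[inside])
}

# pixels within `width`/2 of the segment (x0,y0)-(x1,y1)
rasterize_stroke <- function(x0, y0, x1, y1, width, W, H) {
  r <- width / 2
  bx <- max(0L, floor(min(x0, x1) - r)):min(W - 1L, ceiling(max(x0, x1) + r))
  by <- max(0L, floor(min(y0, y1) - r)):min(H - 1L, ceiling(max(y0, y1) + r))
  gx <- matrix(rep(bx, each = length(by)), length(by))
  gy <- matrix(rep(by, times = length(bx)), length(by))
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((gx - x0) * dx + (gy - y0) * dy) / L2))
  d2 <- (gx - (x0 + t * dx))^2 + (gy - (y0 + t * dy))^2
  inside <- d2 <= r^2
  cbind(x = gx[inside], y = gy[inside])
}

#' Synthetic scene specification
#'
#' Describes one rendered oblique frame: canvas size, the HSV ranges of
#' the vegetation-like background (out of the detector's gamut), a table
#' of flowers (in-gamut filled ellipses), optional distractors, and a
#' speckle-noise rate.  Rendering is deterministic for a fixed `seed`.
#'
#' @param width,height canvas size, px.
#' @param background list of byte ranges `h`, `s`, `v` (each `c(lo, hi)`)
#'   sampled per pixel.
#' @param flowers data frame with columns `cx, cy, w, h` (centre and pixel
#'   extents; centres may be half-integer) and `hue, sat, val` (bytes).
#' @param distractors list of lists; each has `type` (`"stem"` or
#'   `"white_flower"`) plus geometry (`x0, y0, x1, y1, width` for stems;
#'   `cx, cy, w, h` for white flowers) and colour `hue, sat, val`.
#' @param speckle_rate fraction of pixels overwritten with in-gamut
#'   speckle noise.
#' @param speckle_color byte `c(h, s, v)` of the speckle.
#' @param jitter_px boundary jitter amplitude for flowers (<= 1 px;
#'   boundary-band pixels are dropped at random, hulls recorded from the
#'   pixels actually drawn).
#' @param seed integer RNG seed owned by this fixture.
#' @param image_id frame identifier.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 400L, height = 400L,
                       background = list(h = c(70, 100), s = c(80, 200),
                                         v = c(60, 200)),
                       flowers = NULL, distractors = list(),
                       speckle_rate = 0, speckle_color = c(215, 120, 220),
                       jitter_px = 0, seed = 1L, image_id = "scene") {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("canvas must be positive")
  if (is.null(flowers))
    flowers <- data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                          h = numeric(), hue = numeric(), sat = numeric(),
                          val = numeric())
  if (speckle_rate < 0 || speckle_rate > 1) stop("speckle_rate in [0, 1]")
  if (jitter_px < 0 || jitter_px > 1) stop("jitter_px must be in [0, 1]")
  structure(list(width = width, height = height, background = background,
                 flowers = flowers, distractors = distractors,
                 speckle_rate = speckle_rate, speckle_color = speckle_color,
                 jitter_px = jitter_px, seed = as.integer(seed),
                 image_id = image_id),
            class = "scene_spec")
}

#' Render a synthetic scene
#'
#' Draws background, distractors, speckle and flowers (in that order, so
#' flower pixels are never overwritten) and returns the frame together
#' with ground truth.  Truth boxes are the exact rasterised hulls of the
#' planted flowers; distractors are excluded from truth.
#'
#' @param spec a [scene_spec()].
#' @return A list with `image` (a [raster_image()]) and `truth` (data
#'   frame `image_id, x, y, w, h`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$width; H <- spec$height
  fl <- spec$flowers
  if (nrow(fl) > 0L &&
      any(fl$cx - fl$w / 2 < -0.5 | fl$cx + fl$w / 2 > W - 0.5 |
          fl$cy - fl$h / 2 < -0.5 | fl$cy + fl$h / 2 > H - 0.5))
    stop("flower extends outside the canvas")

  with_seed(spec$seed, {
    n <- W * H
    bg <- spec$background
    rgb <- hsv_byte_to_rgb(runif(n, bg$h[1], bg$h[2]),
                           runif(n, bg$s[1], bg$s[2]),
                           runif(n, bg$v[1], bg$v[2]))
    px <- array(0L, c(H, W, 3))
    for (ch in 1:3) px[, , ch] <- matrix(rgb[ch, ], H, W)

    put <- function(pts, h, s, v) {
      if (nrow(pts) == 0L) return(invisible())
      col <- hsv_byte_to_rgb(h, s, v)
      for (ch in 1:3) px[, , ch][cbind(pts[, "y"] + 1L, pts[, "x"] + 1L)] <<- col[ch]
    }

    for (d in spec$distractors) {
      pts <- switch(d$type,
        stem = rasterize_stroke(d$x0, d$y0, d$x1, d$y1, d$width, W, H),
        white_flower = rasterize_ellipse(d$cx, d$cy, d$w, d$h, W, H),
        stop("unknown distractor type: ", d$type))
      put(pts, d$hue, d$sat, d$val)
    }

    if (spec$speckle_rate > 0) {
      hit <- which(runif(n) < spec$speckle_rate)
      if (length(hit) > 0L) {
        sc <- spec$speckle_color
        put(cbind(x = (hit - 1L) %/% H, y = (hit - 1L) %% H),
            sc[1], sc[2], sc[3])
      }
    }

    truth <- data.frame(image_id = character(), x = integer(), y = integer(),
                        w = integer(), h = integer(), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(fl))) {
      pts <- rasterize_ellipse(fl$cx[i], fl$cy[i], fl$w[i], fl$h[i], W, H)
      if (spec$jitter_px > 0 && nrow(pts) > 4L) {
        norm <- ((pts[, "x"] - fl$cx[i]) / (fl$w[i] / 2))^2 +
                ((pts[, "y"] - fl$cy[i]) / (fl$h[i] / 2))^2
        band <- norm > (1 - 2 * spec$jitter_px / max(fl$w[i], fl$h[i]))^2
        drop <- band & runif(nrow(pts)) < 0.25
        pts <- pts[!drop, , drop = FALSE]
      }
      put(pts, fl$hue[i], fl$sat[i], fl$val[i])
      truth <- rbind(truth, data.frame(
        image_id = spec$image_id,
        x = min(pts[, "x"]), y = min(pts[, "y"]),
        w = max(pts[, "x"]) - min(pts[, "x"]) + 1L,
        h = max(pts[, "y"]) - min(pts[, "y"]) + 1L,
        stringsAsFactors = FALSE))
    }

    list(image = raster_image(px, spec$image_id), truth = truth)
  })
}

#' Apparent pixel height of a flower at a given range
#'
#' Inverse of the monocular distance relation:
#' `object_height_px = f * real_height * image_height / (range * sensor_height)`,
#' rounded to the nearest integer.
#'
#' @param world_range_mm camera-to-flower distance, mm.
#' @param real_height_mm true flower height, mm.
#' @param camera a [camera_model()].
#' @return Integer pixel height (>= 1).
#' @examples
#' project_flower(4147.2)  # 38 px for a 43.2 mm flower
#' @export
project_flower <- function(world_range_mm, real_height_mm = 43.2,
                           camera = camera_model()) {
  if (any(world_range_mm <= 0) || real_height_mm <= 0)
    stop("range and height must be positive")
  h <- as.integer(round(camera$focal_mm * real_height_mm *
                          camera$image_height_px /
                          (world_range_mm * camera$sensor_height_mm)))
  if (any(h < 1L))
    stop("object projects below one pixel: out of resolution at this range")
  h
}

# non-overlapping random flower placement; centres snapped so even pixel
# extents sit on half-integer centres (exact rasterised hulls)
place_flowers <- function(n, W, H, h_px, w_px, bounds, margin = 14L) {
  fl <- data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                   h = numeric(), hue = numeric(), sat = numeric(),
                   val = numeric())
  snap <- function(c0, ext) if (ext %% 2L == 1L) round(c0) else round(c0) + 0.5
  lo <- bounds$lower; hi <- bounds$upper
  tries <- 0L
  while (nrow(fl) < n && tries < 4000L) {
    tries <- tries + 1L
    i <- nrow(fl) + 1L
    w <- w_px[i]; h <- h_px[i]
    cx <- snap(runif(1, w / 2 + 1, W - w / 2 - 2), w)
    cy <- snap(runif(1, h / 2 + 1, H - h / 2 - 2), h)
    if (nrow(fl) > 0L &&
        any(abs(fl$cx - cx) < (fl$w + w) / 2 + margin &
            abs(fl$cy - cy) < (fl$h + h) / 2 + margin)) next
    vlo <- if (value_unconstrained(bounds)) 120 else max(lo["v"] + 3, 100)
    vhi <- if (value_unconstrained(bounds)) 240 else hi["v"] - 3
    fl[i, ] <- c(cx, cy, w, h,
                 runif(1, lo["h"] + 4, hi["h"] - 4),
                 runif(1, max(lo["s"] + 4, 60), hi["s"] - 4),
                 runif(1, vlo, vhi))
  }
  if (nrow(fl) < n)
    stop("could not place ", n, " non-overlapping flowers on the canvas")
  fl
}

#' Random clean-scene specification
#'
#' Convenience generator for validation scenes: `n` non-overlapping
#' in-gamut flowers of the given pixel-size range on an out-of-gamut
#' background, all placement and colours drawn from one seeded generator.
#'
#' @param n number of flowers.
#' @param width,height canvas size, px.
#' @param size_range inclusive range of flower pixel heights; widths are
#'   70--90% of heights, floored at `min_width` so every flower passes the
#'   default minimum-size filter.
#' @param min_width smallest flower width, px (default matches the default
#'   [detection_params()] minimum object size).
#' @param bounds the [hsv_bounds()] the flowers must satisfy.
#' @param seed fixture seed.
#' @param image_id frame identifier.
#' @param ... further arguments passed to [scene_spec()] (e.g.
#'   `speckle_rate`, `distractors`, `jitter_px`).
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(n, width = 400L, height = 400L,
                              size_range = c(16L, 30L),
                              bounds = hsv_bounds(c(117, 9, 0), c(230, 200, 0)),
                              min_width = 15L,
                              seed = 1L, image_id = "scene", ...) {
  with_seed(seed, {
    h_px <- sample(size_range[1]:size_range[2], n, replace = TRUE)
    w_px <- pmax(as.integer(min_width),
                 as.integer(round(h_px * runif(n, 0.7, 0.9))))
    fl <- place_flowers(n, width, height, h_px, w_px, bounds)
    scene_spec(width, height, flowers = fl, seed = seed + 1L,
               image_id = image_id, ...)
  })
}

#' Survey specification
#'
#' A simulated riverbank transect: camera poses spaced along a bank
#' polyline at a fixed standoff, yaw facing the bank, and a flower
#' density that is a baseline plus one Gaussian hotspot along the bank.
#' The default reduced-resolution survey camera (608 x 456 px, 1.73 mm
#' sensor height, 8.8 mm focal length) keeps the field-protocol standoff of
#' ~5 m while projecting the 43.2 mm flower to a detectable 17--27 px.
#'
#' @param n_images number of frames along the transect.
#' @param bank matrix with columns `lat, lon`: the riverbank polyline.
#' @param density list with `baseline`, `amplitude` (expected flowers per
#'   frame), `center_frac`, `width_frac` (hotspot position/width as
#'   fractions of the transect).
#' @param standoff_m nominal camera-to-bank distance, metres; per-flower
#'   ranges are drawn in `standoff_m * c(0.8, 1.2)`.
#' @param camera a [camera_model()] for the survey frames.
#' @param bounds flower-colour gamut, an [hsv_bounds()].
#' @param reference_height_mm real flower height, mm.
#' @param seed survey seed.
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(n_images = 30L,
                        bank = rbind(c(53.280, -3.440), c(53.2818, -3.4390)),
                        density = list(baseline = 2, amplitude = 22,
                                       center_frac = 0.5, width_frac = 0.18),
                        standoff_m = 5,
                        camera = camera_model(8.8, 1.73, 73.7, 608L, 456L),
                        bounds = hsv_bounds(c(117, 9, 0), c(230, 200, 0)),
                        reference_height_mm = 43.2,
                        seed = 1L) {
  bank <- as.matrix(bank)
  if (nrow(bank) < 2L) stop("bank polyline needs at least two vertices")
  colnames(bank) <- c("lat", "lon")
  if (any(unlist(density) < 0) || density$width_frac == 0)
    stop("densities must be >= 0 and the hotspot width positive")
  structure(list(n_images = as.integer(n_images), bank = bank,
                 density = density, standoff_m = standoff_m,
                 camera = camera, bounds = bounds,
                 reference_height_mm = reference_height_mm,
                 seed = as.integer(seed)),
            class = "survey_spec")
}

# expected flowers per frame at transect fraction f
survey_density <- function(spec, f) {
  d <- spec$density
  d$baseline + d$amplitude * exp(-(f - d$center_frac)^2 / (2 * d$width_frac^2))
}

# linear interpolation along the bank polyline at fraction f, plus the
# local along-bank bearing (degrees)
bank_point <- function(bank, f) {
  seg_len <- sqrt(diff(bank[, "lat"])^2 + diff(bank[, "lon"])^2)
  cum <- c(0, cumsum(seg_len)) / sum(seg_len)
  i <- max(which(cum <= f + 1e-12)); i <- min(i, nrow(bank) - 1L)
  t <- (f - cum[i]) / (cum[i + 1] - cum[i])
  lat <- unname(bank[i, "lat"] + t * (bank[i + 1, "lat"] - bank[i, "lat"]))
  lon <- unname(bank[i, "lon"] + t * (bank[i + 1, "lon"] - bank[i, "lon"]))
  brg <- geosphere::bearing(c(bank[i, "lon"], bank[i, "lat"]),
                            c(bank[i + 1, "lon"], bank[i + 1, "lat"])) %% 360
  list(lat = lat, lon = lon, along_bearing = brg)
}

#' Generate a synthetic survey fixture set
#'
#' Renders `n_images` frames along the bank transect with per-frame
#' flower counts drawn from the configured density (Poisson, seeded),
#' and writes images (PNG), ground truth, a camera-pose sidecar, the
#' generating density profile and a JSON manifest into `dir`.
#'
#' @param spec a [survey_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list (`images`, `truth_csv`,
#'   `poses_csv`, `density_csv`, `seed`, per-image records).
#' @export
generate_survey <- function(spec, dir) {
  stopifnot(inherits(spec, "survey_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cam <- spec$camera
  W <- cam$image_width_px; H <- cam$image_height_px

  with_seed(spec$seed, {
    truth_all <- NULL; poses <- NULL; dens <- NULL; files <- character()
    for (i in seq_len(spec$n_images)) {
      f <- (i - 0.5) / spec$n_images
      lam <- survey_density(spec, f)
      n <- rpois(1, lam)
      n <- min(n, 35L)  # placement bound on the small canvas
      bp <- bank_point(spec$bank, f)
      # camera stands off the bank on the river side, looking at the bank
      yaw <- (bp$along_bearing + 90) %% 360
      cam_pt <- destination_point(bp$lat, bp$lon, (yaw + 180) %% 360,
                                  spec$standoff_m / 1000)
      id <- sprintf("img%03d", i)

      ranges <- runif(n, spec$standoff_m * 0.8, spec$standoff_m * 1.2) * 1000
      if (n > 0L) {
        h_px <- project_flower(ranges, spec$reference_height_mm, cam)
        w_px <- pmax(9L, as.integer(round(h_px * runif(n, 0.7, 0.9))))
        fl <- place_flowers(n, W, H, h_px, w_px, spec$bounds)
      } else fl <- NULL
      sc <- scene_spec(W, H, flowers = fl,
                       seed = spec$seed + 1000L + i, image_id = id)
      scene <- render_scene(sc)
      path <- file.path(dir, paste0(id, ".png"))
      write_image(scene$image, path)
      files <- c(files, path)
      truth_all <- rbind(truth_all, scene$truth)
      poses <- rbind(poses, data.frame(
        image_id = id, lat = unname(cam_pt["lat"]), lon = unname(cam_pt["lon"]),
        alt_m = 2, yaw_deg = yaw, stringsAsFactors = FALSE))
      dens <- rbind(dens, data.frame(
        image_id = id, frac = f, lambda = lam, n_planted = n,
        stringsAsFactors = FALSE))
    }
    if (is.null(truth_all))
      truth_all <- data.frame(image_id = character(), x = integer(),
                              y = integer(), w = integer(), h = integer())
    rownames(poses) <- NULL
    truth_csv <- file.path(dir, "truth.csv")
    poses_csv <- file.path(dir, "poses.csv")
    density_csv <- file.path(dir, "density.csv")
    write.csv(truth_all, truth_csv, row.names = FALSE)
    write.csv(poses, poses_csv, row.names = FALSE)
    write.csv(dens, density_csv, row.names = FALSE)
    manifest <- list(seed = spec$seed, n_images = spec$n_images,
                     camera = unclass(cam),
                     standoff_m = spec$standoff_m,
                     density = spec$density,
                     images = basename(files),
                     truth_csv = basename(truth_csv),
                     poses_csv = basename(poses_csv),
                     density_csv = basename(density_csv))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  })
}
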