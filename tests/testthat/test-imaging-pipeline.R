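test_that("to_hsv matches the colour-wheel anchors on the full-byte scale", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(255, 0, 0)    # pure red
  px[1, 2, ] <- c(128, 128, 128)  # mid grey
  px[1, 3, ] <- c(0, 0, 255)    # pure blue
  hv <- to_hsv(raster_image(px))
  expect_equal(hv[1, 1, ], c(0L, 255L, 255L))
  expect_equal(hv[1, 2, 2:3], c(0L, 128L))
  expect_equal(hv[1, 3, 1], round(240 / 360 * 255))  # 170
  expect_error(to_hsv(matrix(0, 3, 3)), "3-channel")
})

test_that("threshold_mask selects exactly the in-gamut pixels", {
  b <- default_bounds()
  mk <- function(h, s, v) {
    px <- satt:::hsv_byte_to_rgb(h, s, v)
    raster_image(array(rep(px, each = 25), c(5, 5, 3)))
  }
  expect_true(all(threshold_mask(to_hsv(mk(170, 100, 200)), b)))
  expect_false(any(threshold_mask(to_hsv(mk(245, 100, 200)), b)))  # hue high
  expect_false(any(threshold_mask(to_hsv(mk(80, 100, 200)), b)))   # hue low
  # value channel free when its bounds are (0, 0)
  expect_true(all(threshold_mask(to_hsv(mk(170, 100, 30)), b)))
})

test_that("thresholding a rendered ellipse recovers its rasterised area", {
  fl <- data.frame(cx = 50, cy = 50, w = 21, h = 13,
                   hue = 170, sat = 120, val = 210)
  sc <- render_scene(scene_spec(100, 100, flowers = fl, seed = 3))
  mask <- threshold_mask(to_hsv(sc$image), default_bounds())
  # per-pixel brute force against the ellipse inclusion rule
  cnt <- 0
  for (x in 0:99) for (y in 0:99)
    if (((x - 50) / 10.5)^2 + ((y - 50) / 6.5)^2 < 1) cnt <- cnt + 1
  expect_equal(sum(mask), cnt)
  expect_equal(sc$truth$w[1], 21L)
  expect_equal(sc$truth$h[1], 13L)
})

test_that("apply_mask zeroes exactly the out-of-mask pixels", {
  img <- raster_image(array(7, c(4, 6, 3)))
  expect_equal(unclass(apply_mask(img, matrix(TRUE, 4, 6))), unclass(img),
               ignore_attr = TRUE)
  expect_true(all(apply_mask(img, matrix(FALSE, 4, 6)) == 0))
  half <- matrix(rep(c(TRUE, FALSE), each = 12), 4, 6)
  out <- apply_mask(img, half)
  expect_equal(sum(out == 0), 3 * 12)
  expect_true(all(out[, 1:3, ] == 7))
})

test_that("gaussian_blur is unit-sum, identity at size 1, and rejects even sizes", {
  m <- matrix(5, 20, 20)
  expect_equal(gaussian_blur(m, 15), m)            # constant fixed point
  expect_equal(gaussian_blur(m, 1), m)             # size 1 identity
  spot <- matrix(0, 31, 31); spot[16, 16] <- 1
  sm <- gaussian_blur(spot, 15)
  expect_equal(sum(sm), 1, tolerance = 1e-12)      # mass preserved
  expect_lt(max(sm), 1)                            # peak reduced
  expect_error(gaussian_blur(m, 4), "odd")
})

test_that("contour extraction reports components, hulls and hole hierarchy", {
  expect_length(extract_contours(matrix(FALSE, 8, 8)), 0)

  sq <- matrix(FALSE, 20, 20); sq[6:15, 4:13] <- TRUE
  cs <- extract_contours(sq)
  expect_length(cs, 1)
  expect_equal(unname(cs[[1]]$bbox), c(3, 5, 10, 10))
  expect_equal(cs[[1]]$area, 100)

  ring <- matrix(FALSE, 20, 20); ring[4:15, 4:15] <- TRUE
  ring[8:11, 8:11] <- FALSE
  cs <- extract_contours(ring)
  expect_length(cs, 2)
  holes <- vapply(cs, `[[`, logical(1), "hole")
  expect_equal(sum(holes), 1)
  expect_equal(cs[[which(holes)]]$parent, which(!holes))
})

test_that("minimum-size filtering is inclusive and scores are fill ratios", {
  m <- matrix(FALSE, 30, 30); m[3:6, 3:6] <- TRUE        # 4x4
  expect_length(boxes_from_contours(extract_contours(m), c(6, 7)), 0)

  m <- matrix(FALSE, 30, 30); m[8:22, 10:24] <- TRUE     # 15x15
  bx <- boxes_from_contours(extract_contours(m), c(15, 15))
  expect_length(bx, 1)
  expect_equal(bx[[1]]$score, 1)

  # filled ellipse: fill ratio close to pi/4
  el <- satt:::rasterize_ellipse(30.5, 30.5, 20, 12, 60, 60)
  m <- matrix(FALSE, 60, 60); m[cbind(el[, "y"] + 1, el[, "x"] + 1)] <- TRUE
  bx <- boxes_from_contours(extract_contours(m), c(1, 1))
  expect_equal(bx[[1]]$score, nrow(el) / (20 * 12))      # pixel-count oracle
  expect_equal(bx[[1]]$score, pi / 4, tolerance = 0.06)
})

test_that("detect_flowers finds exactly the planted flowers on clean scenes", {
  for (s in c(2, 9)) {
    n <- c(5, 13)[match(s, c(2, 9))]
    sc <- render_scene(random_scene_spec(n, seed = s))
    boxes <- detect_flowers(sc$image, detection_params())
    expect_length(boxes, n)
    df <- boxes_to_df(boxes)
    # every box is the exact hull of a planted flower
    for (i in seq_len(n)) {
      j <- which(sc$truth$x == df$x[i] & sc$truth$y == df$y[i])
      expect_length(j, 1)
      expect_equal(df$w[i], sc$truth$w[j])
      expect_equal(df$h[i], sc$truth$h[j])
    }
  }
})

test_that("blank out-of-gamut scenes yield no detections", {
  sc <- render_scene(scene_spec(200, 200, seed = 4))
  expect_length(detect_flowers(sc$image, detection_params()), 0)
})

test_that("one-pixel in-gamut speckle is suppressed", {
  sp <- random_scene_spec(6, seed = 21, speckle_rate = 0.01)
  sc <- render_scene(sp)
  expect_length(detect_flowers(sc$image, detection_params()), 6)
})

test_that("detection commutes with horizontal flip", {
  sc <- render_scene(random_scene_spec(7, seed = 31))
  W <- ncol(sc$image)
  flipped <- raster_image(unclass(sc$image)[, W:1, , drop = FALSE])
  a <- boxes_to_df(detect_flowers(sc$image, detection_params()))
  b <- boxes_to_df(detect_flowers(flipped, detection_params()))
  b$x <- W - b$x - b$w   # mirror back
  key <- function(d) d[order(d$x, d$y), c("x", "y", "w", "h")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("returned boxes respect the min-size filter and image bounds", {
  sc <- render_scene(random_scene_spec(10, seed = 41))
  p <- detection_params()
  df <- boxes_to_df(detect_flowers(sc$image, p))
  expect_true(all(df$w >= p$min_size[1] & df$h >= p$min_size[2]))
  expect_true(all(df$x >= 0 & df$y >= 0 &
                  df$x + df$w <= ncol(sc$image) &
                  df$y + df$h <= nrow(sc$image)))
})

test_that("masks only shrink along the morphology chain", {
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(runif(64 * 64) < 0.35, 64, 64)
    s <- shape_search(m, kernel_spec("ellipse", 5, 5))
    n <- noise_opening(s)
    expect_true(all(m[s]))   # s subset of m
    expect_true(all(s[n]))   # n subset of s
  }
})
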