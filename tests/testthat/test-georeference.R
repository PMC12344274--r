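test_that("pinhole distance reproduces the worked example and its scalings", {
  cam <- camera_model()  # f 8.8, sensor 8.8, 3648 px tall
  expect_equal(object_distance_mm(38, 43.2, cam), 43.2 * 3648 / 38)
  expect_equal(object_distance_mm(38, 43.2, cam), 4147.2, tolerance = 1e-4)

  # object filling the frame at unit magnification returns its real height
  expect_equal(object_distance_mm(3648, 43.2, cam), 43.2)
  # inverse proportionality in apparent size
  expect_equal(object_distance_mm(76, 43.2, cam),
               object_distance_mm(38, 43.2, cam) / 2)
  # homogeneity: scaling real and apparent size together changes nothing
  expect_equal(object_distance_mm(19, 21.6, cam),
               object_distance_mm(38, 43.2, cam))
  expect_error(object_distance_mm(0, 43.2, cam), "0 px")
})

test_that("image mean distance is the arithmetic mean and rejects empties", {
  expect_equal(image_mean_distance(1000), 1000)
  expect_equal(image_mean_distance(c(1000, 3000)), 2000)
  expect_equal(image_mean_distance(rep(2500, 7)), 2500)
  expect_error(image_mean_distance(numeric()), "skipped")
})

test_that("side bearings split the FOV about the yaw with wraparound", {
  expect_equal(unname(side_bearings(90, 73.7)), c(53.15, 126.85))
  expect_equal(unname(side_bearings(0, 73.7)), c(323.15, 36.85))
  expect_equal(unname(side_bearings(123.4, 0)), c(123.4, 123.4))
})

test_that("destination point hits the closed-form meridian and equator arcs", {
  expect_equal(destination_point(12.3, 45.6, 77, 0), c(lat = 12.3, lon = 45.6))

  quarter <- pi / 2 * 6378.1
  north <- destination_point(0, 0, 0, quarter)
  expect_equal(unname(north["lat"]), 90, tolerance = 1e-9)

  east <- destination_point(0, 0, 90, 100)
  expect_equal(unname(east["lat"]), 0, tolerance = 1e-12)
  expect_equal(unname(east["lon"]), 100 / 6378.1 * 180 / pi, tolerance = 1e-12)
  expect_error(destination_point(0, 0, 0, -1), ">= 0")
})

test_that("destination point agrees with the independent geodesy library", {
  set.seed(17)
  for (i in 1:50) {
    lat <- runif(1, -80, 80); lon <- runif(1, -179, 179)
    b <- runif(1, 0, 360); d <- runif(1, 0.001, 10)
    mine <- destination_point(lat, lon, b, d)
    ref <- geosphere::destPoint(c(lon, lat), b, d * 1000, r = 6378100)
    expect_equal(unname(mine["lat"]), ref[1, "lat"], tolerance = 1e-9)
    expect_equal(unname(mine["lon"]), ref[1, "lon"], tolerance = 1e-9)
  }
})

test_that("haversine round trip and initial bearing are consistent", {
  set.seed(19)
  for (i in 1:100) {
    lat <- runif(1, -75, 75); lon <- runif(1, -179, 179)
    b <- runif(1, 0, 360); d <- runif(1, 1e-3, 10)
    p <- destination_point(lat, lon, b, d)
    back <- geosphere::distHaversine(c(lon, lat), c(p["lon"], p["lat"]),
                                     r = 6378.1)
    expect_equal(back, d, tolerance = 1e-9)
    b0 <- geosphere::bearing(c(lon, lat), c(p["lon"], p["lat"]), f = 0) %% 360
    expect_lt(min(abs(b0 - b), 360 - abs(b0 - b)), 1e-6)
  }
})

test_that("FOV line geometry is symmetric, chord-accurate and monotone", {
  cam <- camera_model()
  pose <- camera_pose(0, 0, 2, 90)
  fl <- fov_line(pose, cam, 5000, 12)  # 5 m at the equator looking east
  expect_equal(fl$flower_count, 12L)
  expect_equal(fl$flowers_per_meter, 12 / fl$length_m)

  # chord formula in the planar limit: 2 d sin(fov/2)
  chord <- 2 * 5 * sin(73.7 / 2 * pi / 180)
  expect_equal(fl$length_m, chord, tolerance = 1e-4)

  # endpoint bearings sit at yaw -+ fov/2
  for (side in c("left_end", "right_end")) {
    b <- geosphere::bearing(c(0, 0), c(fl[[side]]["lon"], fl[[side]]["lat"]), f = 0) %% 360
    want <- side_bearings(90, 73.7)[[if (side == "left_end") 1 else 2]]
    expect_lt(abs(b - want), 1e-6)
  }

  # zero flowers give zero density; length grows with distance and FOV
  expect_equal(fov_line(pose, cam, 5000, 0)$flowers_per_meter, 0)
  expect_gt(fov_line(pose, cam, 8000, 1)$length_m, fl$length_m)
  wide <- camera_model(fov_deg = 90)
  expect_gt(fov_line(pose, wide, 5000, 1)$length_m, fl$length_m)
})

test_that("image centre point reduces to the destination point along yaw", {
  pose <- camera_pose(53.28, -3.44, 2, 135)
  expect_equal(image_center_point(pose, 0),
               c(lat = 53.28, lon = -3.44))
  expect_equal(image_center_point(pose, 5e6),
               destination_point(53.28, -3.44, 135, 5))
})

test_that("frames without detections are skipped for geolocation", {
  empty <- data.frame(image_id = character(), x = integer(), y = integer(),
                      w = integer(), h = integer(), score = numeric())
  expect_warning(
    g <- geolocate_image(empty, camera_pose(0, 0), camera_model()),
    "skipped")
  expect_null(g)
})

test_that("pose and camera constructors validate their domains", {
  expect_error(camera_pose(95, 0), "latitude")
  expect_error(camera_model(fov_deg = 200), "fov")
  expect_equal(camera_pose(0, 0, yaw_deg = 370)$yaw_deg, 10)
  expect_error(earth_model(-1), "positive")
})
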