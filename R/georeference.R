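#' Camera intrinsics
#'
#' Pinhole-model intrinsics of the survey camera.  Defaults are the DJI
#' Phantom 4 Advanced values: focal length and sensor height both 8.8 mm,
#' a 73.7 degree horizontal field of view, and a 5472 x 3648 px frame.
#'
#' @param focal_mm focal length, mm.
#' @param sensor_height_mm physical sensor height, mm.
#' @param fov_deg horizontal field of view, degrees, in `(0, 180)`.
#' @param image_width_px,image_height_px frame size in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(focal_mm = 8.8, sensor_height_mm = 8.8,
                         fov_deg = 73.7,
                         image_width_px = 5472L, image_height_px = 3648L) {
  if (any(c(focal_mm, sensor_height_mm, image_width_px, image_height_px) <= 0))
    stop("camera parameters must be positive")
  if (fov_deg <= 0 || fov_deg >= 180) stop("`fov_deg` must be in (0, 180)")
  structure(list(focal_mm = focal_mm, sensor_height_mm = sensor_height_mm,
                 fov_deg = fov_deg,
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px)),
            class = "camera_model")
}

#' Per-image camera pose
#'
#' WGS84 position plus gimbal yaw (compass bearing of the image centre,
#' degrees clockwise from true north, normalised to `[0, 360)`).
#'
#' @param lat_deg,lon_deg decimal degrees.
#' @param alt_m altitude above ground, metres.
#' @param yaw_deg gimbal yaw, degrees.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(lat_deg, lon_deg, alt_m = 0, yaw_deg = 0) {
  if (lat_deg < -90 || lat_deg > 90) stop("latitude out of [-90, 90]")
  if (lon_deg < -180 || lon_deg > 180) stop("longitude out of [-180, 180]")
  structure(list(lat_deg = lat_deg, lon_deg = lon_deg, alt_m = alt_m,
                 yaw_deg = yaw_deg %% 360),
            class = "camera_pose")
}

#' Spherical earth model
#'
#' @param radius_km earth radius in km (default 6378.1).
#' @return An object of class `earth_model`.
#' @export
earth_model <- function(radius_km = 6378.1) {
  if (radius_km <= 0) stop("earth radius must be positive")
  structure(list(radius_km = radius_km), class = "earth_model")
}

#' Monocular distance to an object of known size
#'
#' Pinhole-model range from the apparent pixel height of an object whose
#' real height is known:
#' `distance = f * real_height * image_height / (object_height * sensor_height)`.
#' With the default flower height of 43.2 mm this turns every detected
#' bounding box into a camera-to-flower distance.
#'
#' @param object_height_px apparent height of the object, pixels.
#' @param real_height_mm true object height, mm.
#' @param camera a [camera_model()].
#' @return Distance in mm.
#' @examples
#' object_distance_mm(38)  # a 43.2 mm flower spanning 38 px: 4147.2 mm
#' @export
object_distance_mm <- function(object_height_px, real_height_mm = 43.2,
                               camera = camera_model()) {
  if (any(object_height_px == 0))
    stop("object height of 0 px: cannot estimate distance")
  if (any(object_height_px < 0) || real_height_mm <= 0)
    stop("heights must be positive")
  camera$focal_mm * real_height_mm * camera$image_height_px /
    (object_height_px * camera$sensor_height_mm)
}

#' Mean detection distance for an image
#'
#' @param per_box_distance_mm positive per-detection distances, mm.
#' @return Arithmetic mean distance, mm.
#' @export
image_mean_distance <- function(per_box_distance_mm) {
  if (length(per_box_distance_mm) == 0L)
    stop("no detections; image skipped for geolocation")
  if (any(per_box_distance_mm <= 0)) stop("distances must be positive")
  mean(per_box_distance_mm)
}

#' Bearings of the image sides
#'
#' Half the field of view is subtracted from the gimbal yaw for the left
#' image side and added for the right, both normalised to `[0, 360)`.
#'
#' @param yaw_deg gimbal yaw, degrees clockwise from north.
#' @param fov_deg horizontal field of view, degrees.
#' @return Named numeric `c(left, right)` in degrees.
#' @examples
#' side_bearings(90, 73.7)  # c(53.15, 126.85)
#' @export
side_bearings <- function(yaw_deg, fov_deg = 73.7) {
  c(left = (yaw_deg - fov_deg / 2) %% 360,
    right = (yaw_deg + fov_deg / 2) %% 360)
}

#' Great-circle destination point
#'
#' Position reached from `(lat, lon)` travelling `dist_km` along a given
#' initial bearing on a sphere:
#' `lat2 = asin(sin lat1 cos(d/r) + cos lat1 sin(d/r) cos b)`,
#' `lon2 = lon1 + atan2(sin b sin(d/r) cos lat1, cos(d/r) - sin lat1 sin lat2)`.
#' Interfaces in degrees, internal math in radians; longitude normalised to
#' `[-180, 180]`.
#'
#' @param lat_deg,lon_deg origin, decimal degrees.
#' @param bearing_deg initial bearing, degrees clockwise from north.
#' @param dist_km great-circle distance, km (>= 0).
#' @param earth an [earth_model()].
#' @return Named numeric `c(lat, lon)` in degrees.
#' @export
destination_point <- function(lat_deg, lon_deg, bearing_deg, dist_km,
                              earth = earth_model()) {
  if (dist_km < 0) stop("`dist_km` must be >= 0")
  if (dist_km == 0)
    return(c(lat = unname(lat_deg), lon = unname(lon_deg)))
  phi1 <- unname(lat_deg) * pi / 180
  lam1 <- unname(lon_deg) * pi / 180
  b <- unname(bearing_deg) * pi / 180
  delta <- dist_km / earth$radius_km
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(b))
  lam2 <- lam1 + atan2(sin(b) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  lon2 <- ((lam2 * 180 / pi + 180) %% 360) - 180
  c(lat = phi2 * 180 / pi, lon = lon2)
}

#' Image-centre ground point
#'
#' Destination point along the gimbal yaw at the image's mean detection
#' distance: where the frame's detected flowers sit on the map.
#'
#' @param pose a [camera_pose()].
#' @param mean_distance_mm mean detection distance, mm.
#' @param earth an [earth_model()].
#' @return Named numeric `c(lat, lon)`.
#' @export
image_center_point <- function(pose, mean_distance_mm, earth = earth_model()) {
  destination_point(pose$lat_deg, pose$lon_deg, pose$yaw_deg,
                    mean_distance_mm / 1e6, earth)
}

# haversine ground distance in metres on the package's spherical earth
haversine_m <- function(lat1, lon1, lat2, lon2, earth = earth_model()) {
  geosphere::distHaversine(c(lon1, lat1), c(lon2, lat2),
                           r = earth$radius_km * 1000)
}

#' Field-of-view footprint line
#'
#' The ground trace of a frame: destination points along the left and
#' right side bearings at the image's mean detection distance, joined as a
#' line.  Carries the flower count and the flowers-per-meter density
#' (count divided by line length) used as the heatmap weight downstream.
#'
#' @param pose a [camera_pose()].
#' @param camera a [camera_model()].
#' @param mean_distance_mm mean detection distance, mm (> 0).
#' @param flower_count detections in the frame.
#' @param earth an [earth_model()].
#' @return An object of class `fov_line`: list with `left_end`,
#'   `right_end` (each `c(lat, lon)`), `length_m`, `flower_count`,
#'   `flowers_per_meter`.
#' @export
fov_line <- function(pose, camera, mean_distance_mm, flower_count = 0L,
                     earth = earth_model()) {
  if (mean_distance_mm <= 0) stop("`mean_distance_mm` must be positive")
  br <- side_bearings(pose$yaw_deg, camera$fov_deg)
  d_km <- mean_distance_mm / 1e6
  left <- destination_point(pose$lat_deg, pose$lon_deg, br["left"], d_km, earth)
  right <- destination_point(pose$lat_deg, pose$lon_deg, br["right"], d_km, earth)
  len <- haversine_m(left["lat"], left["lon"], right["lat"], right["lon"], earth)
  if (len <= 0) stop("degenerate footprint: zero-length FOV line")
  structure(list(left_end = left, right_end = right, length_m = len,
                 flower_count = as.integer(flower_count),
                 flowers_per_meter = flower_count / len),
            class = "fov_line")
}

#' Georeference one image's detections
#'
#' Converts a frame's detection boxes into a geolocated record: per-box
#' pinhole distances, their mean, the image-centre ground point and the
#' FOV footprint line.
#'
#' @param boxes_df data frame of detections (`x, y, w, h, score`) for one
#'   image, as from [boxes_to_df()].
#' @param pose a [camera_pose()].
#' @param camera a [camera_model()].
#' @param reference_height_mm real flower height, mm.
#' @param earth an [earth_model()].
#' @param image_id frame identifier.
#' @return A list of class `geolocated_image` with elements `image_id`,
#'   `pose`, `flower_count`, `per_box_distance_mm`, `mean_distance_mm`,
#'   `center` and `fov` (an `fov_line`), or `NULL` when the frame has no
#'   detections (such frames are skipped for geolocation).
#' @export
geolocate_image <- function(boxes_df, pose, camera,
                            reference_height_mm = 43.2,
                            earth = earth_model(), image_id = "image") {
  if (nrow(boxes_df) == 0L) {
    warning("no detections in '", image_id, "'; image skipped for geolocation")
    return(NULL)
  }
  d <- object_distance_mm(boxes_df$h, reference_height_mm, camera)
  md <- image_mean_distance(d)
  structure(list(image_id = image_id, pose = pose,
                 flower_count = nrow(boxes_df),
                 per_box_distance_mm = d, mean_distance_mm = md,
                 center = image_center_point(pose, md, earth),
                 fov = fov_line(pose, camera, md, nrow(boxes_df), earth)),
            class = "geolocated_image")
}
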