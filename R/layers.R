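#' Georeference a detection table
#'
#' Joins per-image detections with camera poses and produces the
#' geolocated records and FOV footprint lines for every image that has
#' both a pose and at least one detection; images without detections are
#' skipped for geolocation (with a warning), as are images without poses.
#'
#' @param dets detections data frame (`image_id, x, y, w, h, score`).
#' @param poses pose data frame from [read_pose_sidecar()].
#' @param camera a [camera_model()].
#' @param reference_height_mm real flower height, mm.
#' @param earth an [earth_model()].
#' @return A list of `geolocated_image` records (see [geolocate_image()]).
#' @export
georeference_detections <- function(dets, poses, camera,
                                    reference_height_mm = 43.2,
                                    earth = earth_model()) {
  out <- list()
  for (id in unique(poses$image_id)) {
    pose <- suppressWarnings(read_pose(id, poses))
    if (is.null(pose)) next
    b <- dets[dets$image_id == id, , drop = FALSE]
    g <- suppressWarnings(
      geolocate_image(b, pose, camera, reference_height_mm, earth, id))
    if (!is.null(g)) out[[id]] <- g
  }
  out
}

#' Build GIS layers from geolocated detections
#'
#' Three vector layers mirroring the survey visualisation: the camera
#' capture points (every posed image), the FOV footprint lines and the
#' image-centre flower points (posed images with detections), the latter
#' two carrying `flower_count`, `flowers_per_meter` and
#' `mean_distance_mm` attributes -- the weights used for density/heatmap
#' rendering in GIS software.
#'
#' @param geolocated list of `geolocated_image` records from
#'   [georeference_detections()].
#' @param poses pose data frame (for camera points of images without
#'   detections); defaults to the poses embedded in `geolocated`.
#' @return A named list of three [geo_feature_set()]s: `camera_points`,
#'   `fov_lines`, `flower_points`.
#' @export
build_layers <- function(geolocated, poses = NULL) {
  cam_feats <- list()
  if (!is.null(poses)) {
    for (i in seq_len(nrow(poses)))
      cam_feats[[length(cam_feats) + 1L]] <- list(
        geometry = c(lat = poses$lat[i], lon = poses$lon[i]),
        attributes = list(image_id = poses$image_id[i],
                          yaw_deg = poses$yaw_deg[i]))
  } else {
    for (g in geolocated)
      cam_feats[[length(cam_feats) + 1L]] <- list(
        geometry = c(lat = g$pose$lat_deg, lon = g$pose$lon_deg),
        attributes = list(image_id = g$image_id, yaw_deg = g$pose$yaw_deg))
  }

  line_feats <- list(); pt_feats <- list()
  for (g in geolocated) {
    at <- list(image_id = g$image_id,
               flower_count = g$flower_count,
               flowers_per_meter = g$fov$flowers_per_meter,
               mean_distance_mm = g$mean_distance_mm)
    line_feats[[length(line_feats) + 1L]] <- list(
      geometry = rbind(g$fov$left_end, g$fov$right_end),
      attributes = c(at, list(length_m = g$fov$length_m)))
    pt_feats[[length(pt_feats) + 1L]] <- list(
      geometry = g$center, attributes = at)
  }

  list(camera_points = geo_feature_set("camera_points", "point", cam_feats),
       fov_lines = geo_feature_set("fov_lines", "line", line_feats),
       flower_points = geo_feature_set("flower_points", "point", pt_feats))
}
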