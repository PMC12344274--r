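#' Convert degree-minute-second coordinates to decimal degrees
#'
#' The conversion rule applied to EXIF rational DMS values: southern and
#' western hemisphere references give negative decimals.
#'
#' @param deg,min,sec DMS components.
#' @param ref hemisphere reference, one of `"N", "S", "E", "W"`.
#' @return Decimal degrees.
#' @examples
#' dms_to_decimal(52, 25, 12, "N")  # 52.42
#' @export
dms_to_decimal <- function(deg, min = 0, sec = 0, ref = "N") {
  dec <- deg + min / 60 + sec / 3600
  if (toupper(ref) %in% c("S", "W")) dec <- -dec
  dec
}

#' Read camera poses from a sidecar table
#'
#' The sidecar CSV carries one row per image:
#' `image_id, lat, lon, alt_m, yaw_deg` in decimal degrees / metres.
#' This is the pose source the synthetic fixtures ship with; rows with
#' missing coordinates are skipped with a warning (such images cannot be
#' geolocated).
#'
#' @param path sidecar CSV path.
#' @return A data frame of poses with the columns above.
#' @export
read_pose_sidecar <- function(path) {
  if (!file.exists(path)) stop("no such sidecar file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "lat", "lon", "yaw_deg")
  if (!all(need %in% names(df)))
    stop("sidecar must have columns image_id, lat, lon, yaw_deg")
  if (!"alt_m" %in% names(df)) df$alt_m <- 0
  bad <- is.na(df$lat) | is.na(df$lon) | is.na(df$yaw_deg)
  if (any(bad)) {
    warning("skipping ", sum(bad), " sidecar row(s) with missing pose")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Camera pose for one image
#'
#' Looks an image up in a sidecar pose table and returns its
#' [camera_pose()]; `NULL` (with a warning) when the image has no row,
#' mirroring the per-image skip rule for frames without GPS metadata.
#'
#' @param image_id frame identifier.
#' @param sidecar data frame from [read_pose_sidecar()].
#' @return A [camera_pose()] or `NULL`.
#' @export
read_pose <- function(image_id, sidecar) {
  row <- sidecar[sidecar$image_id == image_id, , drop = FALSE]
  if (nrow(row) == 0L) {
    warning("no pose for image '", image_id, "'; skipping")
    return(NULL)
  }
  camera_pose(row$lat[1], row$lon[1], row$alt_m[1], row$yaw_deg[1])
}

#' Read and write detection tables
#'
#' Per-image detections as CSV with columns
#' `image_id, x, y, w, h, score, distance_mm`.  Writing is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param dets detections data frame (`image_id, x, y, w, h, score` and
#'   optionally `distance_mm`).
#' @param path CSV path.
#' @return `read_detections_csv` returns the data frame;
#'   `write_detections_csv` returns `path` invisibly.
#' @export
write_detections_csv <- function(dets, path) {
  if (!"distance_mm" %in% names(dets)) dets$distance_mm <- NA_real_
  cols <- c("image_id", "x", "y", "w", "h", "score", "distance_mm")
  write.csv(dets[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop("no such detections file: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read ground-truth boxes
#'
#' Accepts the CSV dialect (`image_id, x, y, w, h`) or the annotation
#' JSON written by [write_annotations_json()].
#'
#' @param path CSV or JSON path.
#' @return Data frame `image_id, x, y, w, h`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such ground-truth file: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(recs, function(r) {
      if (length(r$boxes) == 0L) return(NULL)
      do.call(rbind, lapply(r$boxes, function(b)
        data.frame(image_id = r$image_id, x = b$x, y = b$y, w = b$w,
                   h = b$h, stringsAsFactors = FALSE)))
    }))
    if (is.null(df))
      df <- data.frame(image_id = character(), x = integer(), y = integer(),
                       w = integer(), h = integer())
    return(df)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x", "y", "w", "h")
  if (!all(need %in% names(df)))
    stop("ground truth must have columns image_id, x, y, w, h")
  df[, need]
}

#' Write per-image annotation records as JSON
#'
#' One record per image with its box list -- the interchange format for
#' downstream training or re-evaluation.
#'
#' @param dets detections data frame (`image_id, x, y, w, h, score`).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(dets, path) {
  recs <- lapply(unique(dets$image_id), function(id) {
    b <- dets[dets$image_id == id, setdiff(names(dets), "image_id"),
              drop = FALSE]
    rownames(b) <- NULL
    list(image_id = id, boxes = b)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Serialise and restore detection parameters
#'
#' YAML round trip of [detection_params()] with keys mirroring the tuning
#' panel: `hsv.lower`, `hsv.upper`, `kernel.shape`, `kernel.size`,
#' `min_size`, `reference_height_mm`, `blur_size`.
#'
#' @param params a [detection_params()].
#' @param path YAML path.
#' @return `read_params_yaml` returns the [detection_params()];
#'   `write_params_yaml` returns `path` invisibly.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(list(
    hsv = list(lower = as.integer(params$hsv$lower),
               upper = as.integer(params$hsv$upper)),
    blur_size = params$blur_size,
    kernel = list(shape = params$kernel$shape,
                  size = c(params$kernel$width, params$kernel$height)),
    min_size = params$min_size,
    reference_height_mm = params$reference_height_mm), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- detection_params()
  hsv <- if (is.null(cfg$hsv)) defaults$hsv else
    hsv_bounds(unlist(cfg$hsv$lower), unlist(cfg$hsv$upper))
  kernel <- if (is.null(cfg$kernel)) defaults$kernel else
    kernel_spec(cfg$kernel$shape, cfg$kernel$size[1], cfg$kernel$size[2])
  detection_params(
    hsv = hsv,
    blur_size = if (is.null(cfg$blur_size)) defaults$blur_size else cfg$blur_size,
    kernel = kernel,
    min_size = if (is.null(cfg$min_size)) defaults$min_size else unlist(cfg$min_size),
    reference_height_mm = if (is.null(cfg$reference_height_mm))
      defaults$reference_height_mm else cfg$reference_height_mm)
}
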