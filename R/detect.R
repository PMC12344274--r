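#' Detection workflow parameters
#'
#' The full tunable parameter set of the thresholding workflow.  Defaults
#' are the tuned values for the best-conditioned of the three riverbank
#' image sets: hue 117--230 and saturation 9--200 on the full-byte scale
#' with the value channel free, a 15-px Gaussian blur, an elliptical search
#' kernel, a 15 x 15 px minimum object size, and a 43.2 mm reference flower
#' height (field-measured mean of Himalayan balsam flowers, top to bottom).
#'
#' @param hsv an [hsv_bounds()].
#' @param blur_size odd Gaussian kernel width in px.
#' @param kernel a [kernel_spec()] for the shape search.
#' @param min_size integer `(x_px, y_px)`; detections smaller than this in
#'   either axis are discarded (inclusive comparison).
#' @param reference_height_mm real-world flower height used for monocular
#'   distance estimation.
#' @param noise_kernel a [kernel_spec()] for the post-search noise opening.
#' @return An object of class `detection_params`.
#' @examples
#' detection_params(min_size = c(6, 7))
#' @export
detection_params <- function(hsv = hsv_bounds(c(117, 9, 0), c(230, 200, 0)),
                             blur_size = 15L,
                             kernel = kernel_spec("ellipse", 9L, 7L),
                             min_size = c(15L, 15L),
                             reference_height_mm = 43.2,
                             noise_kernel = kernel_spec("ellipse", 3L, 3L)) {
  stopifnot(inherits(hsv, "hsv_bounds"), inherits(kernel, "kernel_spec"),
            inherits(noise_kernel, "kernel_spec"))
  blur_size <- as.integer(blur_size)
  if (blur_size < 1L || blur_size %% 2L == 0L)
    stop("`blur_size` must be odd and >= 1")
  min_size <- as.integer(round(min_size))
  if (length(min_size) != 2L || any(min_size < 1L))
    stop("`min_size` must be two integers >= 1")
  if (!is.numeric(reference_height_mm) || reference_height_mm <= 0)
    stop("`reference_height_mm` must be positive")
  structure(list(hsv = hsv, blur_size = blur_size, kernel = kernel,
                 min_size = min_size,
                 reference_height_mm = as.numeric(reference_height_mm),
                 noise_kernel = noise_kernel),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Detection parameters\n")
  cat("  HSV   : "); print(x$hsv)
  cat("  blur  :", x$blur_size, "px\n")
  cat("  kernel: "); print(x$kernel)
  cat(sprintf("  min size: %d x %d px   reference height: %.1f mm\n",
              x$min_size[1], x$min_size[2], x$reference_height_mm))
  invisible(x)
}

#' Detect flowers in a single frame
#'
#' Runs the semi-automatic thresholding workflow: HSV conversion ->
#' colour thresholding -> masking -> Gaussian smoothing of the chromatic
#' mask with re-binarisation at the 50% level -> elliptical-kernel shape
#' search (opening) -> noise opening -> reconstruction of surviving
#' components at their full chromatic extent -> contour extraction ->
#' minimum-size box filtering.  Deterministic for fixed inputs.
#'
#' The 50% re-binarisation keeps object boundaries in place (a blurred
#' step edge crosses one-half exactly at the edge) while isolated speckle,
#' whose smoothed response is far below one-half, disappears.  The final
#' reconstruction step reports each surviving object at the extent of its
#' original threshold-mask component, so box sizes measure the chromatic
#' object rather than its smoothed silhouette -- which matters because box
#' height feeds the monocular distance estimate.
#'
#' @param image a [raster_image()].
#' @param params a [detection_params()].
#' @return A list of [detection_box()] objects.
#' @export
detect_flowers <- function(image, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  hsvimg <- to_hsv(image)
  m0 <- threshold_mask(hsvimg, params$hsv)

  resp <- gaussian_blur(m0 * 1, params$blur_size)
  m1 <- m0 & (resp >= 0.5)

  m2 <- shape_search(m1, params$kernel)
  m3 <- noise_opening(m2, params$noise_kernel)

  if (!any(m3)) return(list())
  lab0 <- EBImage::bwlabel(m0 * 1L)
  keep <- unique(lab0[m3])
  final <- matrix(lab0 %in% keep, nrow(m0), ncol(m0))

  boxes_from_contours(extract_contours(final), params$min_size)
}
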