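#' HSV threshold bounds
#'
#' Lower and upper hue/saturation/value thresholds on the full-byte scale:
#' hue maps 0--360 degrees onto 0--255 (so the purple-pink hues of balsam
#' flowers sit around 205--230), saturation and value are 0--255.  A value
#' channel given as `lower = upper = 0` means "value unconstrained": tuned
#' parameter tables in the field often leave brightness free so the same
#' bounds work across lighting conditions.
#'
#' @param lower,upper length-3 integer vectors `(h, s, v)`, each in
#'   `[0, 255]`.
#' @return An object of class `hsv_bounds`.
#' @examples
#' hsv_bounds(c(117, 9, 0), c(230, 200, 0))  # value channel free
#' @export
hsv_bounds <- function(lower, upper) {
  lower <- as.integer(round(lower)); upper <- as.integer(round(upper))
  if (length(lower) != 3L || length(upper) != 3L)
    stop("`lower` and `upper` must each be (h, s, v)")
  if (any(lower < 0L) || any(lower > 255L) || any(upper < 0L) || any(upper > 255L))
    stop("HSV components must lie in [0, 255]")
  if (lower[1] > upper[1] || lower[2] > upper[2])
    stop("lower hue/saturation bounds must not exceed the upper bounds")
  structure(list(lower = setNames(lower, c("h", "s", "v")),
                 upper = setNames(upper, c("h", "s", "v"))),
            class = "hsv_bounds")
}

#' @export
print.hsv_bounds <- function(x, ...) {
  v <- if (value_unconstrained(x)) "free" else
    sprintf("%d..%d", x$lower["v"], x$upper["v"])
  cat(sprintf("<hsv_bounds H %d..%d  S %d..%d  V %s>\n",
              x$lower["h"], x$upper["h"], x$lower["s"], x$upper["s"], v))
  invisible(x)
}

value_unconstrained <- function(bounds) {
  bounds$lower["v"] == 0L && bounds$upper["v"] == 0L
}

#' Convert an RGB image to full-byte HSV
#'
#' Hue encodes 0--360 degrees mapped onto 0--255; saturation and value are
#' each 0--255.  Pure greys have saturation 0.
#'
#' @param image a [raster_image()].
#' @return An integer `H x W x 3` array of HSV values.
#' @examples
#' img <- raster_image(array(c(0, 0, 255), c(1, 1, 3)), "blue")
#' to_hsv(img)[1, 1, ]  # hue 170 = 240 degrees on the byte scale
#' @export
to_hsv <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("to_hsv() needs a 3-channel RGB image")
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv01 <- rgb2hsv(rgb, maxColorValue = 255)
  out <- array(0L, d)
  out[, , 1] <- as.integer(round(hsv01[1, ] * 255))
  out[, , 2] <- as.integer(round(hsv01[2, ] * 255))
  out[, , 3] <- as.integer(round(hsv01[3, ] * 255))
  out
}

#' Threshold an HSV image into a binary mask
#'
#' A pixel is foreground when every constrained channel lies within
#' `[lower, upper]` inclusive.  The value channel is unconstrained when
#' both its bounds are 0 (see [hsv_bounds()]).
#'
#' @param hsv_image an `H x W x 3` HSV array from [to_hsv()].
#' @param bounds an [hsv_bounds()].
#' @return A logical `H x W` matrix (`TRUE` = in gamut).
#' @export
threshold_mask <- function(hsv_image, bounds) {
  if (length(dim(hsv_image)) != 3L || dim(hsv_image)[3] != 3L)
    stop("`hsv_image` must be an H x W x 3 HSV array")
  lo <- bounds$lower; hi <- bounds$upper
  m <- hsv_image[, , 1] >= lo["h"] & hsv_image[, , 1] <= hi["h"] &
       hsv_image[, , 2] >= lo["s"] & hsv_image[, , 2] <= hi["s"]
  if (!value_unconstrained(bounds))
    m <- m & hsv_image[, , 3] >= lo["v"] & hsv_image[, , 3] <= hi["v"]
  m
}

#' Zero out-of-mask pixels of an image
#'
#' @param image a [raster_image()].
#' @param mask a logical `H x W` matrix of matching dimensions.
#' @return A [raster_image()] with out-of-mask pixels set to 0.
#' @export
apply_mask <- function(image, mask) {
  d <- dim(image)
  if (!is.logical(mask) || nrow(mask) != d[1] || ncol(mask) != d[2])
    stop("mask dimensions must match the image")
  px <- unclass(image)
  for (ch in 1:3) px[, , ch][!mask] <- 0L
  raster_image(px, image_id(image))
}
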