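#' Raster image container
#'
#' An RGB frame held as an `H x W x 3` array of 8-bit intensities
#' (0--255, RGB channel order) with an `image_id` attribute.  This is the
#' unit of processing for the detection workflow: one oblique UAV frame.
#'
#' @param pixels numeric array `H x W x 3` with values in `[0, 255]`.
#' @param image_id character scalar identifying the frame.
#' @return An object of class `raster_image`.
#' @examples
#' px <- array(0, c(4, 6, 3))
#' img <- raster_image(px, "blank")
#' dim(img)
#' @export
raster_image <- function(pixels, image_id = "image") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array (RGB)")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have positive height and width")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  pixels <- array(as.integer(round(pixels)), dim(pixels))
  structure(pixels, image_id = as.character(image_id),
            class = c("raster_image", "array"))
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image '%s': %d x %d px, 3 channels>\n",
              image_id(x), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname raster_image
#' @param x a `raster_image`.
#' @export
image_id <- function(x) {
  id <- attr(x, "image_id")
  if (is.null(id)) "image" else id
}

#' Read a raster image from disk
#'
#' Decodes a PNG or TIFF file into a [raster_image()].  The `image_id`
#' defaults to the file name without extension.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param image_id optional frame identifier.
#' @return A [raster_image()].
#' @export
read_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '.", ext, "' (PNG and TIFF are supported)")
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  raster_image(round(px * 255), image_id)
}

#' Write a raster image to disk
#'
#' @param image a [raster_image()].
#' @param path output path; format chosen by extension (`.png`, `.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(px, path),
    tif  = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported raster format '.", ext, "'")
  )
  invisible(path)
}
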