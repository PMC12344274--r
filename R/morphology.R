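#' Structuring-element specification
#'
#' The footprint used by the morphological shape search.  An elliptical
#' element mirrors the front-facing outline of a balsam flower; cross and
#' rectangle shapes suit other flower geometries (e.g. cruciform
#' brassicas).
#'
#' @param shape one of `"ellipse"`, `"cross"`, `"rectangle"`.
#' @param width,height footprint size in pixels (each >= 1).
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("ellipse", 7, 5)
#' @export
kernel_spec <- function(shape = c("ellipse", "cross", "rectangle"),
                        width = 9L, height = 7L) {
  shape <- match.arg(shape)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("kernel width and height must be >= 1")
  structure(list(shape = shape, width = width, height = height),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec %s %dx%d>\n", x$shape, x$width, x$height))
  invisible(x)
}

#' Rasterise a structuring element
#'
#' Returns the element as a logical `height x width` matrix.  Elliptical
#' elements use semi-axes `width/2`, `height/2` about the footprint centre,
#' so width/height give the exact pixel span and the smallest (3x3)
#' ellipse is the full block.
#'
#' @param kernel a [kernel_spec()].
#' @return Logical matrix of the footprint.
#' @export
structuring_element <- function(kernel) {
  w <- kernel$width; h <- kernel$height
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  el <- switch(kernel$shape,
    rectangle = matrix(TRUE, h, w),
    cross     = x == floor(cx) | y == floor(cy),
    ellipse   = {
      a <- w / 2; b <- h / 2
      ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1 + 1e-9
    })
  el
}

# offsets (dy, dx) of the TRUE cells of a structuring element, relative to
# its integer anchor (the floor-centre cell)
element_offsets <- function(kernel) {
  el <- structuring_element(kernel)
  ay <- (nrow(el) - 1L) %/% 2L
  ax <- (ncol(el) - 1L) %/% 2L
  idx <- which(el, arr.ind = TRUE)
  cbind(dy = idx[, 1] - 1L - ay, dx = idx[, 2] - 1L - ax)
}

# translate a logical matrix so out[p] = m[p + (dy, dx)], FALSE off-grid
shift_mask <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L - dy):min(nr, nr - dy)
  cs <- max(1L, 1L - dx):min(nc, nc - dx)
  if (length(rs) > 0L && length(cs) > 0L && rs[1] <= rs[length(rs)])
    out[rs, cs] <- m[rs + dy, cs + dx]
  out
}

#' Binary erosion, dilation and opening
#'
#' Minkowski morphology on logical masks with an arbitrary structuring
#' element; off-image pixels count as background.  `open_mask()` is erosion
#' followed by dilation and is idempotent.
#'
#' @param mask logical `H x W` matrix.
#' @param kernel a [kernel_spec()].
#' @return A logical matrix of the same dimensions.
#' @export
erode_mask <- function(mask, kernel) {
  off <- element_offsets(kernel)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off[i, 1], off[i, 2])
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, kernel) {
  off <- element_offsets(kernel)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))            # reflected element
    out <- out | shift_mask(mask, -off[i, 1], -off[i, 2])
  out
}

#' @rdname erode_mask
#' @export
open_mask <- function(mask, kernel) {
  dilate_mask(erode_mask(mask, kernel), kernel)
}

#' Elliptical-kernel shape search
#'
#' Morphological opening with the configured structuring element: only
#' regions that can contain the full kernel footprint survive, which is how
#' the workflow expresses its ellipse shape prior.  The result is always a
#' subset of the input mask.
#'
#' @param mask logical `H x W` matrix.
#' @param kernel a [kernel_spec()]; must fit inside the mask.
#' @return The opened mask.
#' @export
shape_search <- function(mask, kernel) {
  if (kernel$height > nrow(mask) || kernel$width > ncol(mask))
    stop("kernel is larger than the mask")
  open_mask(mask, kernel)
}

#' Noise-suppression opening
#'
#' Opening with a small fixed elliptical element (default 3x3) to remove
#' isolated pixels and tiny clusters left by thresholding.
#'
#' @param mask logical `H x W` matrix.
#' @param kernel a [kernel_spec()]; defaults to a 3x3 ellipse.
#' @return The opened mask.
#' @export
noise_opening <- function(mask, kernel = kernel_spec("ellipse", 3L, 3L)) {
  shape_search(mask, kernel)
}
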