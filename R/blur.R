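# Separable Gaussian smoothing with reflect padding.  The sigma follows the
# usual kernel-size relation sigma = 0.3*((size-1)/2 - 1) + 0.8, so the
# default 15-px blur has sigma = 2.6.

gaussian_kernel_1d <- function(size) {
  if (size == 1L) return(1)
  sigma <- 0.3 * ((size - 1) * 0.5 - 1) + 0.8
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect-pad indices for a vector of length n and half-width r:
# index i-r..i+r with mirror at the edges (no repeated edge pixel)
reflect_index <- function(n, shift) {
  idx <- seq_len(n) + shift
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  ifelse(idx > n, 2L * n - idx, idx)
}

convolve_axis <- function(m, k, margin) {
  r <- (length(k) - 1L) / 2L
  n <- if (margin == 1L) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    idx <- reflect_index(n, j - 1L - r)
    out <- out + k[j] * (if (margin == 1L) m[idx, , drop = FALSE]
                         else m[, idx, drop = FALSE])
  }
  out
}

#' Gaussian blur
#'
#' Separable `size x size` Gaussian convolution with reflect padding at the
#' borders.  Works on a single-channel matrix or a 3-channel image; constant
#' inputs are fixed points and `size = 1` is the identity.
#'
#' @param image a numeric matrix, an `H x W x 3` array or a
#'   [raster_image()].
#' @param size odd kernel width in pixels (the workflow default is 15).
#' @return The blurred input, same type and dimensions.
#' @export
gaussian_blur <- function(image, size = 15L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("blur `size` must be an odd positive integer")
  k <- gaussian_kernel_1d(size)
  blur2d <- function(m) convolve_axis(convolve_axis(m, k, 1L), k, 2L)
  if (is.matrix(image)) return(blur2d(image))
  d <- dim(image)
  if (length(d) != 3L) stop("expected a matrix or an H x W x C array")
  id <- attr(image, "image_id")
  out <- array(0, d)
  for (ch in seq_len(d[3])) out[, , ch] <- blur2d(image[, , ch])
  if (inherits(image, "raster_image")) raster_image(round(out), id) else out
}
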