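#' Extract contours from a binary mask
#'
#' One outer contour per 4-connected foreground component, plus one inner
#' contour per enclosed hole, with a containment hierarchy (each hole
#' records its parent outer contour).  Component labelling, hole filling
#' and boundary tracing are delegated to EBImage.
#'
#' @param mask logical `H x W` matrix.
#' @return A list of contours; each is a list with elements
#'   `points` (n x 2 matrix of 0-based `(x, y)` boundary vertices),
#'   `hole` (logical), `parent` (index of the enclosing outer contour, or
#'   `NA`), `area` (pixel count of the region) and `bbox`
#'   (`c(x, y, w, h)`, the axis-aligned hull).  Empty mask gives an empty
#'   list.
#' @export
extract_contours <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("`mask` must be a logical matrix")
  if (!any(mask)) return(list())

  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  tr <- EBImage::ocontour(lab)          # per-label (row-1, col-1) chains

  contour_of <- function(labmat, i, chain, hole, parent) {
    idx <- which(labmat == i, arr.ind = TRUE)
    x0 <- min(idx[, 2]) - 1L; y0 <- min(idx[, 1]) - 1L
    w <- max(idx[, 2]) - min(idx[, 2]) + 1L
    h <- max(idx[, 1]) - min(idx[, 1]) + 1L
    pts <- cbind(x = chain[, 2], y = chain[, 1])   # ocontour is (row, col)
    list(points = pts, hole = hole, parent = parent,
         area = nrow(idx), bbox = c(x = x0, y = y0, w = w, h = h))
  }

  out <- lapply(seq_len(n), function(i)
    contour_of(lab, i, tr[[i]], hole = FALSE, parent = NA_integer_))

  filled <- EBImage::fillHull(mask * 1L) > 0
  holes <- filled & !mask
  if (any(holes)) {
    hlab <- EBImage::bwlabel(holes * 1L)
    htr <- EBImage::ocontour(hlab)
    for (i in seq_len(max(hlab))) {
      idx <- which(hlab == i, arr.ind = TRUE)
      top <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
      parent <- lab[top[1], top[2] - 1L]  # pixel left of the hole is foreground
      out[[length(out) + 1L]] <-
        contour_of(hlab, i, htr[[i]], hole = TRUE, parent = as.integer(parent))
    }
  }
  out
}

#' Detection bounding box
#'
#' One detected flower candidate: the axis-aligned hull of an outer
#' contour, 0-based top-left origin, with a fill-ratio pseudo-score (region
#' area over box area, in `(0, 1]`) that ranks compact elliptical blobs
#' above straggly ones.
#'
#' @param x,y,w,h box position and extent in pixels.
#' @param contour n x 2 matrix of `(x, y)` boundary vertices.
#' @param score fill ratio in `(0, 1]`.
#' @return An object of class `detection_box`.
#' @export
detection_box <- function(x, y, w, h, contour, score) {
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h),
                 contour = contour, score = as.numeric(score)),
            class = "detection_box")
}

#' @export
print.detection_box <- function(x, ...) {
  cat(sprintf("<detection_box (%d,%d) %dx%d score %.3f>\n",
              x$x, x$y, x$w, x$h, x$score))
  invisible(x)
}

#' Bounding boxes from contours with minimum-size filtering
#'
#' One box per outer contour whose hull is at least `min_size` in both
#' axes (inclusive); hole contours are ignored.  Exactly identical boxes
#' are deduplicated.
#'
#' @param contours output of [extract_contours()].
#' @param min_size integer `(x_px, y_px)` minimum hull extents.
#' @return A list of [detection_box()] objects.
#' @export
boxes_from_contours <- function(contours, min_size = c(1L, 1L)) {
  min_size <- as.integer(round(min_size))
  if (length(min_size) != 2L || any(min_size < 1L))
    stop("`min_size` must be two integers >= 1")
  boxes <- list()
  seen <- character()
  for (cn in contours) {
    if (isTRUE(cn$hole)) next
    bb <- cn$bbox
    if (bb["w"] < min_size[1] || bb["h"] < min_size[2]) next
    key <- paste(bb, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    score <- min(1, cn$area / (as.numeric(bb["w"]) * as.numeric(bb["h"])))
    boxes[[length(boxes) + 1L]] <-
      detection_box(bb["x"], bb["y"], bb["w"], bb["h"], cn$points, score)
  }
  boxes
}

#' Convert detection boxes to a data frame
#'
#' @param boxes list of [detection_box()] objects.
#' @param image_id frame identifier to attach.
#' @return A data frame with columns `image_id, x, y, w, h, score`.
#' @export
boxes_to_df <- function(boxes, image_id = "image") {
  if (length(boxes) == 0L)
    return(data.frame(image_id = character(), x = integer(), y = integer(),
                      w = integer(), h = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(image_id = image_id,
             x = vapply(boxes, `[[`, integer(1), "x"),
             y = vapply(boxes, `[[`, integer(1), "y"),
             w = vapply(boxes, `[[`, integer(1), "w"),
             h = vapply(boxes, `[[`, integer(1), "h"),
             score = vapply(boxes, `[[`, numeric(1), "score"),
             stringsAsFactors = FALSE)
}
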