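#' Intersection over union of two boxes
#'
#' Boxes are `(x, y, w, h)` with 0-based top-left origin; IoU is the
#' intersection area divided by the union area, 0 for disjoint boxes.
#'
#' @param a,b numeric vectors or lists with elements `x, y, w, h`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ax <- a[["x"]]; ay <- a[["y"]]; aw <- a[["w"]]; ah <- a[["h"]]
  bx <- b[["x"]]; by <- b[["y"]]; bw <- b[["w"]]; bh <- b[["h"]]
  if (aw <= 0 || ah <= 0 || bw <= 0 || bh <= 0)
    stop("boxes must have positive area")
  ix <- max(0, min(ax + aw, bx + bw) - max(ax, bx))
  iy <- max(0, min(ay + ah, by + bh) - max(ay, by))
  inter <- ix * iy
  inter / (aw * ah + bw * bh - inter)
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching: detections are taken in descending score
#' order and each claims the highest-IoU still-unmatched truth box with
#' IoU at or above `iou_min`.  Unmatched detections are false positives;
#' unmatched truths are false negatives.  A single detection spanning a
#' bunch of flowers therefore counts one true positive and leaves the
#' remaining flowers as misses.
#'
#' @param dets data frame of detections (`x, y, w, h, score`).
#' @param truths data frame of ground-truth boxes (`x, y, w, h`).
#' @param iou_min matching threshold (default 0.5).
#' @return A list of class `match_outcome`: `tp`, `fp`, `fn` counts and
#'   `matched_pairs` (data frame `det, truth, iou` of 1-based indices).
#' @export
match_detections <- function(dets, truths, iou_min = 0.5) {
  nd <- nrow(dets); nt <- nrow(truths)
  pairs <- data.frame(det = integer(), truth = integer(), iou = numeric())
  if (nd > 0L && nt > 0L) {
    ord <- order(-dets$score, seq_len(nd))
    taken <- rep(FALSE, nt)
    for (i in ord) {
      ious <- vapply(seq_len(nt), function(j)
        if (taken[j]) -1 else box_iou(dets[i, ], truths[j, ]), numeric(1))
      j <- which.max(ious)
      if (length(j) == 1L && ious[j] >= iou_min) {
        taken[j] <- TRUE
        pairs <- rbind(pairs, data.frame(det = i, truth = j, iou = ious[j]))
      }
    }
  }
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs),
                 fn = nt - nrow(pairs), matched_pairs = pairs),
            class = "match_outcome")
}

#' Precision, recall and F1
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2 p r / (p + r)`.  A degenerate denominator returns 0 with a
#' warning so batch evaluation never aborts.
#'
#' @param tp,fp,fn non-negative counts.
#' @param p,r precision and recall.
#' @return A number in `[0, 1]`.
#' @export
precision_score <- function(tp, fp) {
  if (tp + fp == 0) {
    warning("precision undefined (no detections); returning 0")
    return(0)
  }
  tp / (tp + fp)
}

#' @rdname precision_score
#' @export
recall_score <- function(tp, fn) {
  if (tp + fn == 0) {
    warning("recall undefined (no ground truth); returning 0")
    return(0)
  }
  tp / (tp + fn)
}

#' @rdname precision_score
#' @export
f1_score <- function(p, r) {
  if (p + r == 0) {
    warning("F1 undefined (precision + recall = 0); returning 0")
    return(0)
  }
  2 * p * r / (p + r)
}

#' Precision-recall curve over a detection set
#'
#' Sweeps the score threshold over all distinct detection scores in
#' descending order; at each threshold the detections at or above it are
#' matched per image and pooled precision/recall over the whole image set
#' form one operating point.  Points are returned in recall-ascending
#' order.
#'
#' @param dets data frame of detections over all images
#'   (`image_id, x, y, w, h, score`).
#' @param truths data frame of truths over all images
#'   (`image_id, x, y, w, h`).
#' @param iou_min matching threshold.
#' @return A data frame with columns `recall`, `precision` (class
#'   `pr_curve`).
#' @export
pr_curve <- function(dets, truths, iou_min = 0.5) {
  if (nrow(truths) == 0L) stop("no ground truth anywhere: recall undefined")
  if (nrow(dets) == 0L)
    return(structure(data.frame(recall = numeric(), precision = numeric()),
                     class = c("pr_curve", "data.frame")))
  thresholds <- sort(unique(dets$score), decreasing = TRUE)
  pts <- t(vapply(thresholds, function(thr) {
    kept <- dets[dets$score >= thr, , drop = FALSE]
    tp <- 0L; fp <- 0L
    for (id in unique(c(kept$image_id, truths$image_id))) {
      m <- match_detections(kept[kept$image_id == id, , drop = FALSE],
                            truths[truths$image_id == id, , drop = FALSE],
                            iou_min)
      tp <- tp + m$tp; fp <- fp + m$fp
    }
    c(recall = tp / nrow(truths), precision = if (tp + fp == 0) 0 else tp / (tp + fp))
  }, c(recall = 0, precision = 0)))
  out <- as.data.frame(pts)[order(pts[, "recall"]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pr_curve", "data.frame"))
}

#' 11-point interpolated average precision
#'
#' `AP = mean over r in {0, 0.1, ..., 1} of max precision at recall >= r`
#' (0 where no operating point reaches `r`).
#'
#' @param curve a [pr_curve()] or data frame with `recall`, `precision`.
#' @return AP in `[0, 1]`.
#' @examples
#' eleven_point_ap(data.frame(recall = c(0.2, 0.6),
#'                            precision = c(1.0, 0.5)))  # 5/11
#' @export
eleven_point_ap <- function(curve) {
  if (nrow(curve) == 0L) return(0)
  levels <- seq(0, 1, by = 0.1)
  interp <- vapply(levels, function(r) {
    at <- curve$precision[curve$recall >= r - 1e-12]
    if (length(at) == 0L) 0 else max(at)
  }, numeric(1))
  mean(interp)
}

#' Mean average precision over classes
#'
#' @param aps per-class average precisions (non-empty).
#' @return Their arithmetic mean.  With a single detected class (one
#'   flower species) mAP equals AP.
#' @export
mean_ap <- function(aps) {
  if (length(aps) == 0L) stop("`aps` must be non-empty")
  mean(aps)
}

#' Evaluate detections against ground truth
#'
#' Pools per-image matching into global precision/recall/F1 at the raw
#' operating point, plus the 11-point interpolated AP (= mAP for the
#' single flower class) from the score-swept precision-recall curve.
#'
#' @param dets detections data frame (`image_id, x, y, w, h, score`).
#' @param truths truths data frame (`image_id, x, y, w, h`).
#' @param iou_min matching threshold.
#' @return A list of class `satt_eval`: `per_image` data frame
#'   (`image_id, tp, fp, fn`), `tp, fp, fn`, `precision`, `recall`, `f1`,
#'   `ap`, `map`, and the `curve`.
#' @export
evaluate_detections <- function(dets, truths, iou_min = 0.5) {
  ids <- unique(c(dets$image_id, truths$image_id))
  per <- do.call(rbind, lapply(ids, function(id) {
    m <- match_detections(dets[dets$image_id == id, , drop = FALSE],
                          truths[truths$image_id == id, , drop = FALSE],
                          iou_min)
    data.frame(image_id = id, tp = m$tp, fp = m$fp, fn = m$fn)
  }))
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  p <- suppressWarnings(precision_score(tp, fp))
  r <- suppressWarnings(recall_score(tp, fn))
  curve <- pr_curve(dets, truths, iou_min)
  ap <- eleven_point_ap(curve)
  structure(list(per_image = per, tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r,
                 f1 = suppressWarnings(f1_score(p, r)),
                 ap = ap, map = mean_ap(ap), curve = curve),
            class = "satt_eval")
}

#' @export
print.satt_eval <- function(x, ...) {
  cat(sprintf(
    "Detection evaluation: %d TP, %d FP, %d FN\n  precision %.3f  recall %.3f  F1 %.3f  AP(11-pt) %.3f  mAP %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$ap, x$map))
  invisible(x)
}
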