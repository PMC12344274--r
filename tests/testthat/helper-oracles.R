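# Independent brute-force oracles: deliberately naive per-pixel /
# per-threshold implementations, structurally different from the package's
# vectorised code paths.

# erosion: pixel survives iff every element cell translated to it is inside
# the mask; dilation: pixel turns on iff the reflected element hits the mask
bf_erode <- function(mask, el, anchor) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  cells <- which(el, arr.ind = TRUE)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    ok <- TRUE
    for (k in seq_len(nrow(cells))) {
      rr <- r + cells[k, 1] - anchor[1]
      cc <- c + cells[k, 2] - anchor[2]
      if (rr < 1 || rr > H || cc < 1 || cc > W || !mask[rr, cc]) {
        ok <- FALSE; break
      }
    }
    out[r, c] <- ok
  }
  out
}

bf_dilate <- function(mask, el, anchor) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  cells <- which(el, arr.ind = TRUE)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    hit <- FALSE
    for (k in seq_len(nrow(cells))) {
      rr <- r - (cells[k, 1] - anchor[1])
      cc <- c - (cells[k, 2] - anchor[2])
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) {
        hit <- TRUE; break
      }
    }
    out[r, c] <- hit
  }
  out
}

bf_open <- function(mask, kernel) {
  el <- structuring_element(kernel)
  anchor <- c((nrow(el) - 1) %/% 2 + 1, (ncol(el) - 1) %/% 2 + 1)
  bf_dilate(bf_erode(mask, el, anchor), el, anchor)
}

# literal 11-point interpolation: mean over the 11 recall levels of the
# maximum precision at recall >= level
bf_eleven_point_ap <- function(curve) {
  total <- 0
  for (r in seq(0, 1, by = 0.1)) {
    best <- 0
    for (i in seq_len(nrow(curve)))
      if (curve$recall[i] >= r - 1e-12 && curve$precision[i] > best)
        best <- curve$precision[i]
    total <- total + best
  }
  total / 11
}

# cumulative sweep (VOC-style): flag each detection TP/FP in global
# descending score order with per-image greedy matching, then cumulate
bf_pr_curve <- function(dets, truths, iou_min = 0.5) {
  ord <- order(-dets$score)
  taken <- list()
  is_tp <- logical(nrow(dets))
  for (i in ord) {
    id <- dets$image_id[i]
    tr <- truths[truths$image_id == id, , drop = FALSE]
    if (is.null(taken[[id]])) taken[[id]] <- rep(FALSE, nrow(tr))
    best <- 0; bj <- 0
    for (j in seq_len(nrow(tr))) {
      if (taken[[id]][j]) next
      v <- box_iou(dets[i, ], tr[j, ])
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= iou_min) { taken[[id]][bj] <- TRUE; is_tp[i] <- TRUE }
  }
  scores <- dets$score[ord]
  cum_tp <- cumsum(is_tp[ord])
  cum_fp <- cumsum(!is_tp[ord])
  keep <- !duplicated(scores, fromLast = TRUE)  # one point per distinct score
  data.frame(recall = (cum_tp / nrow(truths))[keep],
             precision = (cum_tp / (cum_tp + cum_fp))[keep])
}

# random boxes + scores over a few images, for metric property tests
random_detection_set <- function(seed, n_images = 3) {
  set.seed(seed)
  truths <- do.call(rbind, lapply(seq_len(n_images), function(i) {
    n <- sample(1:6, 1)
    data.frame(image_id = paste0("im", i),
               x = sample(0:80, n), y = sample(0:80, n),
               w = sample(8:20, n, replace = TRUE),
               h = sample(8:20, n, replace = TRUE))
  }))
  dets <- do.call(rbind, lapply(seq_len(n_images), function(i) {
    tr <- truths[truths$image_id == paste0("im", i), ]
    n <- sample(1:8, 1)
    base <- tr[sample(nrow(tr), n, replace = TRUE), ]
    data.frame(image_id = base$image_id,
               x = pmax(0, base$x + sample(-6:6, n, replace = TRUE)),
               y = pmax(0, base$y + sample(-6:6, n, replace = TRUE)),
               w = pmax(4, base$w + sample(-3:3, n, replace = TRUE)),
               h = pmax(4, base$h + sample(-3:3, n, replace = TRUE)),
               score = round(runif(n), 3))
  }))
  list(dets = dets, truths = truths)
}
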