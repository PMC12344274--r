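box <- function(x, y, w, h) list(x = x, y = y, w = w, h = h)

test_that("IoU covers identical, disjoint and partial overlap", {
  expect_equal(box_iou(box(0, 0, 10, 10), box(0, 0, 10, 10)), 1)
  expect_equal(box_iou(box(0, 0, 10, 10), box(30, 30, 5, 5)), 0)
  expect_equal(box_iou(box(0, 0, 10, 10), box(5, 0, 10, 10)), 1 / 3)
  expect_error(box_iou(box(0, 0, 0, 5), box(0, 0, 3, 3)), "positive area")
})

test_that("greedy matching is one-to-one with score priority", {
  tr <- data.frame(image_id = "a", x = 0, y = 0, w = 10, h = 10)
  d2 <- data.frame(image_id = "a", x = c(0, 1), y = c(0, 0),
                   w = 10, h = 10, score = c(0.9, 0.8))
  m <- match_detections(d2, tr)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
  expect_equal(m$matched_pairs$det, 1)  # higher score claims the truth

  exact <- data.frame(image_id = "a", x = c(0, 20), y = c(0, 20),
                      w = 8, h = 8, score = 0.5)
  tr2 <- exact[, setdiff(names(exact), "score")]
  m <- match_detections(exact, tr2)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 0, 0))

  m <- match_detections(exact[0, ], tr2)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 0, 2))
})

test_that("matching is invariant to the ordering of truth boxes", {
  set.seed(3)
  for (s in 1:5) {
    rs <- random_detection_set(s, n_images = 1)
    m1 <- match_detections(rs$dets, rs$truths)
    m2 <- match_detections(rs$dets, rs$truths[rev(seq_len(nrow(rs$truths))), ])
    expect_equal(c(m1$tp, m1$fp, m1$fn), c(m2$tp, m2$fp, m2$fn))
  }
})

test_that("precision, recall and F1 follow the count formulas", {
  p <- precision_score(8, 2); r <- recall_score(8, 2)
  expect_equal(c(p, r, f1_score(p, r)), c(0.8, 0.8, 0.8))
  expect_warning(expect_equal(precision_score(0, 0), 0), "undefined")
  expect_warning(expect_equal(recall_score(0, 0), 0), "undefined")
  expect_warning(expect_equal(f1_score(0, 0), 0), "undefined")
  expect_equal(f1_score(1, 1), 1)
})

test_that("F1 is bounded by the arithmetic mean and by 1", {
  set.seed(7)
  for (i in 1:25) {
    p <- runif(1); r <- runif(1)
    f <- f1_score(p, r)
    expect_lte(f, (p + r) / 2 + 1e-12)
    expect_lte(f, 1)
    expect_gte(f, 0)
  }
})

test_that("the PR sweep equals the cumulative-threshold oracle", {
  # worked toy set: 5 scored detections over 3 truths
  tr <- data.frame(image_id = "a", x = c(0, 20, 40), y = 0, w = 10, h = 10)
  de <- data.frame(image_id = "a",
                   x = c(0, 20, 60, 40, 80), y = 0, w = 10, h = 10,
                   score = c(0.9, 0.8, 0.7, 0.6, 0.5))
  cv <- pr_curve(de, tr)
  expect_equal(cv$recall, c(1, 2, 2, 3, 3) / 3)
  expect_equal(cv$precision, c(1, 1, 2 / 3, 3 / 4, 3 / 5))
  expect_equal(as.data.frame(cv), bf_pr_curve(de, tr), ignore_attr = TRUE)

  for (s in 1:6) {
    rs <- random_detection_set(s)
    expect_equal(as.data.frame(pr_curve(rs$dets, rs$truths)),
                 bf_pr_curve(rs$dets, rs$truths),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(pr_curve(de, tr[0, ]), "recall undefined")
})

test_that("all-correct and all-wrong detection sets give the extreme curves", {
  tr <- data.frame(image_id = "a", x = c(0, 20, 40), y = 0, w = 10, h = 10)
  good <- cbind(tr, score = c(0.9, 0.5, 0.7))
  cv <- pr_curve(good, tr)
  expect_equal(cv$recall, (1:3) / 3)
  expect_true(all(cv$precision == 1))
  expect_equal(eleven_point_ap(cv), 1)

  bad <- data.frame(image_id = "a", x = 200, y = 200, w = 5, h = 5, score = 0.9)
  expect_true(all(pr_curve(bad, tr)$precision == 0))
})

test_that("11-point AP interpolates the worked curve to 5/11", {
  cv <- data.frame(recall = c(0.2, 0.6), precision = c(1.0, 0.5))
  expect_equal(eleven_point_ap(cv), 5 / 11)
  expect_equal(eleven_point_ap(cv[0, ]), 0)
  expect_equal(eleven_point_ap(data.frame(recall = 1, precision = 1)), 1)
})

test_that("11-point AP equals the literal interpolation on random curves", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    cv <- data.frame(recall = sort(runif(n)), precision = runif(n))
    expect_equal(eleven_point_ap(cv), bf_eleven_point_ap(cv),
                 tolerance = 1e-13)
  }
})

test_that("relabelling a false positive as true never lowers AP", {
  tr <- data.frame(image_id = "a", x = c(0, 20, 40, 60), y = 0, w = 10, h = 10)
  de <- data.frame(image_id = "a", x = c(0, 20, 100, 60), y = 0, w = 10, h = 10,
                   score = c(0.9, 0.8, 0.7, 0.6))
  ap_before <- eleven_point_ap(pr_curve(de, tr))
  de$x[3] <- 40  # the false positive now hits a truth
  ap_after <- eleven_point_ap(pr_curve(de, tr))
  expect_gte(ap_after, ap_before)
})

test_that("mAP averages per-class APs and reproduces the three-set mean", {
  expect_equal(mean_ap(0.5), 0.5)
  expect_equal(mean_ap(c(1, 0)), 0.5)
  expect_equal(mean_ap(c(0.857, 0.854, 0.729)), 0.8133333, tolerance = 1e-7)
  expect_error(mean_ap(numeric()), "non-empty")
})

test_that("evaluate_detections pools per-image counts into global scores", {
  tr <- data.frame(image_id = rep(c("a", "b"), each = 2),
                   x = c(0, 30, 0, 30), y = 0, w = 10, h = 10)
  de <- cbind(tr[c(1, 2, 3), ], score = c(0.9, 0.8, 0.7))
  de <- rbind(de, data.frame(image_id = "b", x = 200, y = 200, w = 10, h = 10,
                             score = 0.6))
  ev <- evaluate_detections(de, tr)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(3, 1, 1))
  expect_equal(ev$precision, 3 / 4)
  expect_equal(ev$recall, 3 / 4)
  expect_equal(ev$f1, 0.75)
  expect_equal(ev$map, ev$ap)   # single class
})
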