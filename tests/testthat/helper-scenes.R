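# Deterministic grid-layout scenes for degradation experiments: large
# flowers (detectable), optional sub-minimum flowers (true but too small),
# stem distractors (in flower hue, elongated) and speckle noise.

grid_positions <- function(k, W, H, cell = 90) {
  per_row <- floor((W - cell) / cell) + 1
  i <- seq_len(k) - 1
  cbind(x = cell / 2 + (i %% per_row) * cell + 20,
        y = cell / 2 + (i %/% per_row) * cell + 20)
}

grid_scene <- function(n_big = 6, n_small = 0, n_stems = 0,
                       speckle_rate = 0, seed = 1, W = 400, H = 400,
                       image_id = "scene") {
  set.seed(seed)
  k <- n_big + n_small + n_stems
  pos <- grid_positions(k, W, H)
  stopifnot(max(pos[, "y"]) < H - 40)
  slot <- sample(seq_len(k))  # shuffle which cell gets what

  fl <- NULL
  idx <- 1
  for (i in seq_len(n_big)) {
    h <- sample(18:28, 1); w <- max(15, round(h * runif(1, 0.75, 0.9)))
    fl <- rbind(fl, data.frame(
      cx = pos[slot[idx], "x"] + (w %% 2 == 0) * 0.5,
      cy = pos[slot[idx], "y"] + (h %% 2 == 0) * 0.5,
      w = w, h = h, hue = runif(1, 125, 222), sat = runif(1, 60, 190),
      val = runif(1, 130, 235)))
    idx <- idx + 1
  }
  for (i in seq_len(n_small)) {
    fl <- rbind(fl, data.frame(
      cx = pos[slot[idx], "x"], cy = pos[slot[idx], "y"],
      w = 7, h = 9, hue = runif(1, 125, 222), sat = runif(1, 60, 190),
      val = runif(1, 130, 235)))
    idx <- idx + 1
  }
  distract <- list()
  for (i in seq_len(n_stems)) {
    cx <- pos[slot[idx], "x"]; cy <- pos[slot[idx], "y"]
    distract[[i]] <- list(type = "stem", x0 = cx - 14, y0 = cy - 24,
                          x1 = cx + 14, y1 = cy + 24, width = 12,
                          hue = runif(1, 125, 222), sat = runif(1, 60, 190),
                          val = 235)
    idx <- idx + 1
  }
  scene_spec(W, H, flowers = fl, distractors = distract,
             speckle_rate = speckle_rate, seed = seed + 500,
             image_id = image_id)
}

# render a batch of scenes and pool detections + truth
run_batch <- function(specs, params) {
  dets <- NULL; truth <- NULL
  for (sp in specs) {
    sc <- render_scene(sp)
    dets <- rbind(dets, boxes_to_df(detect_flowers(sc$image, params),
                                    sp$image_id))
    truth <- rbind(truth, sc$truth)
  }
  list(dets = dets, truth = truth)
}

default_bounds <- function() hsv_bounds(c(117, 9, 0), c(230, 200, 0))
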