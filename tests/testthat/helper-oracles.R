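# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the implementations they verify.

# recursive/stack flood-fill count of 1-valued connected components
flood_fill_count <- function(mask, connectivity = 4) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  moves <- if (connectivity == 4) {
    cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  } else {
    cbind(c(1, -1, 0, 0, 1, 1, -1, -1), c(0, 0, 1, -1, 1, -1, 1, -1))
  }
  count <- 0L
  for (x0 in seq_len(W)) {
    for (y0 in seq_len(H)) {
      if (mask[y0, x0] != 1 || seen[y0, x0]) next
      count <- count + 1L
      stack_y <- integer(H * W); stack_x <- integer(H * W)
      top <- 1L; stack_y[1] <- y0; stack_x[1] <- x0
      seen[y0, x0] <- TRUE
      while (top > 0L) {
        y <- stack_y[top]; x <- stack_x[top]; top <- top - 1L
        for (m in seq_len(nrow(moves))) {
          yy <- y + moves[m, 1]; xx <- x + moves[m, 2]
          if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
              mask[yy, xx] == 1 && !seen[yy, xx]) {
            seen[yy, xx] <- TRUE
            top <- top + 1L
            stack_y[top] <- yy; stack_x[top] <- xx
          }
        }
      }
    }
  }
  count
}

# brute-force bilateral filter: literal double loop over the window
bilateral_bruteforce <- function(img, radius, sigma_range, sigma_space) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      acc <- 0; wsum <- 0
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          yy <- y + dy; xx <- x + dx
          if (yy < 1 || yy > H || xx < 1 || xx > W) next
          w <- exp(-(dx^2 + dy^2) / (2 * sigma_space^2)) *
            exp(-(img[yy, xx] - img[y, x])^2 / (2 * sigma_range^2))
          acc <- acc + w * img[yy, xx]
          wsum <- wsum + w
        }
      }
      out[y, x] <- acc / wsum
    }
  }
  out
}

# exhaustive threshold-sweep average precision: evaluates precision/recall
# at every score cutoff and integrates the upper precision envelope over
# recall levels
ap_threshold_sweep <- function(detections, truths, iou_thr = 0.6) {
  if (!"image_id" %in% names(detections)) detections$image_id <- "img"
  if (!"image_id" %in% names(truths)) truths$image_id <- "img"
  n_truth <- nrow(truths)
  det <- detections[order(-detections$score, detections$xmin, detections$ymin), ]
  # greedy matching flags for the full ordered list (a prefix of the order
  # is exactly the detection set above any score cutoff)
  tp <- logical(nrow(det))
  matched <- rep(FALSE, n_truth)
  for (i in seq_len(nrow(det))) {
    best_j <- 0; best_iou <- iou_thr
    for (j in seq_len(n_truth)) {
      if (matched[j] || truths$image_id[j] != det$image_id[i]) next
      ix <- max(0, min(det$xmax[i], truths$xmax[j]) - max(det$xmin[i], truths$xmin[j]))
      iy <- max(0, min(det$ymax[i], truths$ymax[j]) - max(det$ymin[i], truths$ymin[j]))
      inter <- ix * iy
      un <- (det$xmax[i] - det$xmin[i]) * (det$ymax[i] - det$ymin[i]) +
        (truths$xmax[j] - truths$xmin[j]) * (truths$ymax[j] - truths$ymin[j]) - inter
      v <- inter / un
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0) { tp[i] <- TRUE; matched[best_j] <- TRUE }
  }
  prec <- rec <- numeric(nrow(det))
  for (k in seq_len(nrow(det))) {       # every cutoff = every prefix
    prec[k] <- sum(tp[1:k]) / k
    rec[k] <- sum(tp[1:k]) / n_truth
  }
  ap <- 0
  levels <- sort(unique(rec))
  prev <- 0
  for (r in levels) {
    p_max <- max(prec[rec >= r])
    ap <- ap + (r - prev) * p_max
    prev <- r
  }
  ap
}

# random scored detection instance on a small canvas, for AP checks
random_detection_instance <- function(seed) {
  set.seed(seed)
  n_t <- sample(1:5, 1)
  x0 <- runif(n_t, 0, 60); y0 <- runif(n_t, 0, 60)
  tr <- stoma_boxes(xmin = x0, ymin = y0, xmax = x0 + runif(n_t, 8, 25),
                    ymax = y0 + runif(n_t, 8, 25))
  n_d <- sample(1:8, 1)
  base <- tr[sample(n_t, n_d, replace = TRUE), ]
  jit <- runif(n_d, 0, 12)
  de <- stoma_boxes(xmin = base$xmin + jit, ymin = base$ymin + jit,
                    xmax = base$xmax + jit, ymax = base$ymax + jit,
                    score = round(runif(n_d), 3))
  list(detections = de, truths = tr)
}
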