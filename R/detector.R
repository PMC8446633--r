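#' Detector configuration
#'
#' Configuration of the anchor-based stomata detector. The full-scale
#' protocol resizes inputs to 800 x 600, uses anchor scales {4, 8, 16} and
#' aspect ratios {0.5, 1, 2}, batch size 16, and cosine annealing of the
#' learning rate from 5e-4 to 5e-5 over 20 epochs; the two-term training
#' loss weighs the box-regression term by `lambda_reg = 10` and both
#' network stages' class/box terms equally. The default backbone is a small
#' residual network trained from scratch (desk scale); `widths` deepens it.
#'
#' @param input_size `c(width, height)` images are resized to; each must be
#'   divisible by the backbone stride `2^length(widths)`.
#' @param anchor_scales Anchor side = scale x stride pixels.
#' @param anchor_ratios Anchor aspect ratios (height/width).
#' @param batch_size Images per gradient step.
#' @param lr_initial,lr_final Cosine-annealed learning-rate endpoints.
#' @param epochs Training epochs (>= 1).
#' @param lambda_reg Weight of the box-regression loss term.
#' @param backbone Backbone identifier (informational; `widths` defines the
#'   desk-scale residual backbone).
#' @param pretrained Whether to start from injected pretrained backbone
#'   weights (none ship with the package).
#' @param widths Channel widths of the residual blocks; the stride is
#'   `2^length(widths)`.
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param score_min Score floor applied before NMS at detection time.
#' @param n_sample,pos_frac Anchor minibatch size and positive fraction.
#' @param seed Integer seed.
#' @return Object of class `stomx_det_config`.
#' @export
detector_config <- function(input_size = c(800, 600), anchor_scales = c(4, 8, 16),
                            anchor_ratios = c(0.5, 1, 2), batch_size = 16,
                            lr_initial = 5e-4, lr_final = 5e-5, epochs = 20,
                            lambda_reg = 10, backbone = "resnet-tiny",
                            pretrained = FALSE, widths = c(16, 32, 64),
                            nms_iou = 0.5, score_min = 0.05,
                            n_sample = 128, pos_frac = 0.5, seed = 1L) {
  stopifnot(lr_final < lr_initial, epochs >= 1, all(anchor_scales > 0),
            all(anchor_ratios > 0), batch_size >= 1, lambda_reg >= 0)
  stride <- 2^length(widths)
  if (any(input_size %% stride != 0)) {
    abort("input_size must be divisible by the backbone stride")
  }
  structure(
    list(input_size = as.integer(input_size), anchor_scales = anchor_scales,
         anchor_ratios = anchor_ratios, batch_size = as.integer(batch_size),
         lr_initial = lr_initial, lr_final = lr_final,
         epochs = as.integer(epochs), lambda_reg = lambda_reg,
         backbone = backbone, pretrained = isTRUE(pretrained),
         widths = as.integer(widths), stride = as.integer(stride),
         nms_iou = nms_iou, score_min = score_min,
         n_sample = as.integer(n_sample), pos_frac = pos_frac,
         seed = as.integer(seed)),
    class = "stomx_det_config"
  )
}

#' Smooth-L1 loss kernel
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise: quadratic near zero,
#' linear in the tails, continuous at `|x| = 1`.
#'
#' @param x Numeric vector of residuals.
#' @return Non-negative numeric vector.
#' @export
smooth_l1 <- function(x) {
  stopifnot(all(is.finite(x)))
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

#' Two-term detector loss
#'
#' Reference implementation of the detector objective:
#' `(1/N_cls) sum CE(p_i, p_i*) + lambda (1/N_reg) sum_{positives}
#' smooth_l1(t_i - t_i*)` where the cross-entropy is over class
#' probabilities and the regression sum runs coordinatewise over positive
#' anchors. With no positive anchors the regression term is zero.
#'
#' @param class_probs `n x 2` matrix of class probabilities (background,
#'   stoma).
#' @param class_targets Length-`n` vector of 0 (background) / 1 (stoma);
#'   `NA` entries are ignored anchors.
#' @param box_deltas,box_targets `n x 4` matrices of predicted and target
#'   box deltas (used on positive anchors).
#' @param cfg A [detector_config()] (supplies `lambda_reg`).
#' @return Non-negative scalar loss.
#' @export
detector_loss <- function(class_probs, class_targets, box_deltas, box_targets,
                          cfg = detector_config()) {
  keep <- !is.na(class_targets)
  n_cls <- sum(keep)
  stopifnot(n_cls > 0)
  pt <- ifelse(class_targets[keep] == 1, class_probs[keep, 2], class_probs[keep, 1])
  l_cls <- mean(-log(pmax(pt, 1e-12)))
  pos <- which(!is.na(class_targets) & class_targets == 1)
  l_reg <- 0
  if (length(pos) > 0) {
    res <- box_deltas[pos, , drop = FALSE] - box_targets[pos, , drop = FALSE]
    l_reg <- cfg$lambda_reg * sum(smooth_l1(res)) / length(pos)
  }
  l_cls + l_reg
}

# ---- anchors -----------------------------------------------------------

# anchor table for a feature map of fw x fh cells: matrix n x 4 (cx, cy, w,
# h) in input-image pixels, ordered so row index matches the C++ anchor id
# (x * fh + y) * A + a, with a running over scales (outer) and ratios (inner)
anchor_grid <- function(cfg) {
  fw <- cfg$input_size[1] %/% cfg$stride
  fh <- cfg$input_size[2] %/% cfg$stride
  shapes <- expand.grid(ratio = cfg$anchor_ratios, scale = cfg$anchor_scales)
  side <- shapes$scale * cfg$stride
  aw <- side / sqrt(shapes$ratio)
  ah <- side * sqrt(shapes$ratio)
  A <- nrow(shapes)
  n <- fw * fh * A
  cx <- numeric(n); cy <- numeric(n); w <- numeric(n); h <- numeric(n)
  i <- 1
  for (x in 0:(fw - 1)) {
    for (y in 0:(fh - 1)) {
      for (a in 1:A) {
        cx[i] <- (x + 0.5) * cfg$stride
        cy[i] <- (y + 0.5) * cfg$stride
        w[i] <- aw[a]; h[i] <- ah[a]
        i <- i + 1
      }
    }
  }
  cbind(cx = cx, cy = cy, w = w, h = h)
}

anchors_xyxy <- function(anchors) {
  tibble(xmin = anchors[, "cx"] - anchors[, "w"] / 2,
         ymin = anchors[, "cy"] - anchors[, "h"] / 2,
         xmax = anchors[, "cx"] + anchors[, "w"] / 2,
         ymax = anchors[, "cy"] + anchors[, "h"] / 2)
}

# assign training labels to anchors: positives are anchors with IoU >=
# pos_iou to some ground-truth box, plus the best anchor of each box; all
# other anchors are negative candidates (no ignore band: anchors just
# below the positive threshold otherwise never see a negative label, fire
# confidently at test time and duplicate the count with shifted boxes).
# A balanced minibatch of n_sample anchors is kept; half of the negative
# budget is drawn from the near-object ring (IoU in [0.1, neg_iou)) so the
# classifier learns to reject almost-aligned boxes, the rest uniformly.
assign_anchors <- function(anchors, gt, cfg, pos_iou = 0.5, neg_iou = 0.5) {
  n <- nrow(anchors)
  labels <- rep(-1L, n)
  reg_t <- matrix(0, 4, n)
  if (is.null(gt) || nrow(gt) == 0) {
    cand <- seq_len(n)
    neg <- sample(cand, min(cfg$n_sample, n))
    labels[neg] <- 0L
    return(list(labels = labels, reg_t = reg_t))
  }
  iou <- box_iou_matrix(anchors_xyxy(anchors), gt)
  max_iou <- apply(iou, 1, max)
  best_gt <- max.col(iou, ties.method = "first")
  pos <- which(max_iou >= pos_iou)
  best_anchor <- apply(iou, 2, which.max)
  pos <- union(pos, best_anchor[apply(iou, 2, max) > 0])
  n_pos <- min(length(pos), round(cfg$n_sample * cfg$pos_frac))
  if (length(pos) > n_pos) pos <- sample(pos, n_pos)
  n_neg_budget <- cfg$n_sample - length(pos)
  ring <- setdiff(which(max_iou >= 0.1 & max_iou < neg_iou), pos)
  easy <- setdiff(which(max_iou < 0.1), pos)
  n_ring <- min(length(ring), n_neg_budget %/% 2)
  if (length(ring) > n_ring) ring <- sample(ring, n_ring)
  n_easy <- min(length(easy), n_neg_budget - length(ring))
  if (length(easy) > n_easy) easy <- sample(easy, n_easy)
  labels[c(ring, easy)] <- 0L
  labels[pos] <- 1L
  if (length(pos)) {
    g <- best_gt[pos]
    gw <- gt$xmax[g] - gt$xmin[g]; gh <- gt$ymax[g] - gt$ymin[g]
    gx <- gt$xmin[g] + gw / 2; gy <- gt$ymin[g] + gh / 2
    reg_t[1, pos] <- (gx - anchors[pos, "cx"]) / anchors[pos, "w"]
    reg_t[2, pos] <- (gy - anchors[pos, "cy"]) / anchors[pos, "h"]
    reg_t[3, pos] <- log(gw / anchors[pos, "w"])
    reg_t[4, pos] <- log(gh / anchors[pos, "h"])
  }
  list(labels = labels, reg_t = reg_t)
}

# detector parameter list (backbone residual blocks + head) under the
# current RNG; class-logit biases start at (0, -2) so initial stoma scores
# are low
det_init_params <- function(cfg, in_ch = 3) {
  A <- length(cfg$anchor_scales) * length(cfg$anchor_ratios)
  p <- list()
  cin <- in_ch
  for (wd in cfg$widths) {
    p <- c(p, kaiming_conv(wd, cin * 9))
    p <- c(p, kaiming_conv(wd, wd * 9))
    cin <- wd
  }
  p <- c(p, kaiming_conv(cin, cin * 9))
  head <- kaiming_conv(A * 6, cin)
  head[[1]] <- head[[1]] * 0.1
  bias <- numeric(A * 6)
  bias[seq_len(A) * 2] <- -2
  head[[2]] <- bias
  c(p, head)
}

# resize a training/inference image to the detector input and rescale boxes
det_prepare <- function(mic, boxes, cfg) {
  px <- as_pixel_array(mic)
  h0 <- dim(px)[1]; w0 <- dim(px)[2]
  w <- cfg$input_size[1]; h <- cfg$input_size[2]
  if (h0 != h || w0 != w) px <- resize_image(px, h, w, "bilinear")
  x <- px / 255 - 0.5
  sx <- w / w0; sy <- h / h0
  if (!is.null(boxes) && nrow(boxes)) {
    boxes$xmin <- boxes$xmin * sx; boxes$xmax <- boxes$xmax * sx
    boxes$ymin <- boxes$ymin * sy; boxes$ymax <- boxes$ymax * sy
  }
  list(x = x, boxes = boxes, sx = sx, sy = sy)
}

#' Train the stomata detector
#'
#' Seeded training of the anchor-based detector on annotated images:
#' anchors are labeled against the ground-truth boxes each epoch (balanced
#' minibatch sampling), and the two-term loss ([detector_loss()] form) is
#' minimized with Adam under the cosine learning-rate schedule.
#'
#' @param train_set List of records, each a list with `micrograph` (or
#'   `image`) and `boxes`.
#' @param cfg A [detector_config()].
#' @param verbose Print per-epoch progress.
#' @return Object of class `stomx_detector` with `params`, `cfg` and a
#'   training `log` tibble (per-epoch total/classification/regression loss).
#' @export
train_detector <- function(train_set, cfg = detector_config(), verbose = FALSE) {
  if (length(train_set) == 0) abort("empty training set")
  stopifnot(cfg$epochs >= 1)
  with_seed(cfg$seed, {
    params <- det_init_params(cfg)
    fit <- det_train_loop(params, train_set, cfg, verbose)
    structure(list(params = fit$params, cfg = cfg, log = fit$log),
              class = "stomx_detector")
  })
}

det_train_loop <- function(params, train_set, cfg, verbose) {
  anchors <- anchor_grid(cfg)
  A <- length(cfg$anchor_scales) * length(cfg$anchor_ratios)
  prep <- lapply(train_set, function(rec) {
    mic <- rec$micrograph %||% rec$image
    det_prepare(mic, rec$boxes, cfg)
  })
  state <- adam_init(params)
  n <- length(prep)
  log_rows <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1, cfg)
    ord <- sample.int(n)
    tot <- cls <- reg <- numeric(0)
    for (b in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b:min(b + cfg$batch_size - 1, n)]
      acc <- NULL
      for (i in idx) {
        asg <- assign_anchors(anchors, prep[[i]]$boxes, cfg)
        st <- .cpp_det_step(params, prep[[i]]$x, length(cfg$widths), A,
                            asg$labels, asg$reg_t, cfg$lambda_reg)
        if (!is.finite(st$loss)) {
          abort(sprintf("non-finite detector loss at epoch %d", epoch))
        }
        acc <- grads_accumulate(acc, st$grads)
        tot <- c(tot, st$loss); cls <- c(cls, st$loss_cls); reg <- c(reg, st$loss_reg)
      }
      upd <- adam_update(params, grads_scale(acc, 1 / length(idx)), state, lr)
      params <- upd$params; state <- upd$state
    }
    log_rows[[epoch]] <- tibble(epoch = epoch, lr = lr, loss = mean(tot),
                                loss_cls = mean(cls), loss_reg = mean(reg))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f (cls %.4f reg %.4f)",
                      epoch, lr, mean(tot), mean(cls), mean(reg)))
    }
  }
  list(params = params, log = dplyr::bind_rows(log_rows))
}

#' Fine-tune a trained detector on new data
#'
#' Transfer-learning protocol: all layers are updated from the checkpoint
#' with a smaller cosine-annealed initial rate (default 1e-4 over 20
#' epochs, annealing to a tenth). `lr_initial = 0` returns the checkpoint
#' unchanged.
#'
#' @param model Trained `stomx_detector` (the checkpoint).
#' @param new_train_set Annotated records for the new image family.
#' @param lr_initial,epochs Fine-tuning schedule.
#' @param verbose Print progress.
#' @param seed Seed for the fine-tuning run.
#' @return A new `stomx_detector`.
#' @export
finetune_detector <- function(model, new_train_set, lr_initial = 1e-4,
                              epochs = 20, verbose = FALSE, seed = 1L) {
  stopifnot(inherits(model, "stomx_detector"), length(new_train_set) >= 1)
  cfg <- model$cfg
  cfg$lr_initial <- lr_initial
  cfg$lr_final <- lr_initial / 10
  cfg$epochs <- as.integer(epochs)
  cfg$seed <- as.integer(seed)
  if (lr_initial == 0) {
    return(structure(list(params = model$params, cfg = model$cfg,
                          log = model$log), class = "stomx_detector"))
  }
  with_seed(cfg$seed, {
    fit <- det_train_loop(model$params, new_train_set, cfg, verbose)
    structure(list(params = fit$params, cfg = cfg, log = fit$log),
              class = "stomx_detector")
  })
}

# deterministic non-maximum suppression; ties in score broken by (xmin, ymin)
nms_boxes <- function(boxes, iou_thr) {
  if (nrow(boxes) <= 1) return(boxes)
  ord <- order(-boxes$score, boxes$xmin, boxes$ymin)
  x1 <- boxes$xmin[ord]; y1 <- boxes$ymin[ord]
  x2 <- boxes$xmax[ord]; y2 <- boxes$ymax[ord]
  area <- (x2 - x1) * (y2 - y1)
  n <- length(ord)
  keep <- logical(n)
  kept <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept)) {
      iw <- pmax(0, pmin(x2[i], x2[kept]) - pmax(x1[i], x1[kept]))
      ih <- pmax(0, pmin(y2[i], y2[kept]) - pmax(y1[i], y1[kept]))
      inter <- iw * ih
      if (max(inter / (area[i] + area[kept] - inter)) > iou_thr) next
    }
    keep[i] <- TRUE
    kept <- c(kept, i)
  }
  boxes[ord[keep], ]
}

#' Run the detector on a micrograph
#'
#' Produces scored stoma boxes: the network scores every anchor, box deltas
#' are decoded, boxes are clipped to the image, low scores are dropped and
#' non-maximum suppression removes overlapping detections. Deterministic
#' for a fixed model and image.
#'
#' @param model Trained `stomx_detector`.
#' @param mic Micrograph or pixel array.
#' @param nms_iou IoU threshold for NMS (default from the config).
#' @return Box tibble with `score`, sorted by decreasing score, in the
#'   original image's coordinates.
#' @export
detect_stomata <- function(model, mic, nms_iou = NULL) {
  stopifnot(inherits(model, "stomx_detector"))
  cfg <- model$cfg
  nms_iou <- nms_iou %||% cfg$nms_iou
  prep <- det_prepare(mic, NULL, cfg)
  A <- length(cfg$anchor_scales) * length(cfg$anchor_ratios)
  out <- .cpp_det_forward(model$params, prep$x, length(cfg$widths))
  fh <- dim(out)[1]; fw <- dim(out)[2]
  anchors <- anchor_grid(cfg)
  n <- nrow(anchors)
  # per-anchor foreground probability and deltas, in anchor-id order
  l0 <- numeric(n); l1 <- numeric(n); dl <- matrix(0, n, 4)
  aid <- 1
  for (x in 0:(fw - 1)) {
    for (y in 0:(fh - 1)) {
      for (a in 0:(A - 1)) {
        l0[aid] <- out[y + 1, x + 1, 2 * a + 1]
        l1[aid] <- out[y + 1, x + 1, 2 * a + 2]
        dl[aid, ] <- out[y + 1, x + 1, 2 * A + 4 * a + 1:4]
        aid <- aid + 1
      }
    }
  }
  m <- pmax(l0, l1)
  score <- exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
  cx <- anchors[, "cx"] + dl[, 1] * anchors[, "w"]
  cy <- anchors[, "cy"] + dl[, 2] * anchors[, "h"]
  w <- anchors[, "w"] * exp(clamp(dl[, 3], -4, 4))
  h <- anchors[, "h"] * exp(clamp(dl[, 4], -4, 4))
  boxes <- stoma_boxes(xmin = cx - w / 2, ymin = cy - h / 2,
                       xmax = cx + w / 2, ymax = cy + h / 2,
                       score = clamp(score, 0, 1))
  boxes <- boxes[boxes$score >= cfg$score_min, ]
  if (nrow(boxes) > 600) {  # pre-NMS cap on candidates
    boxes <- boxes[order(-boxes$score, boxes$xmin, boxes$ymin)[1:600], ]
  }
  boxes <- clip_boxes(boxes, cfg$input_size[1], cfg$input_size[2])
  boxes <- nms_boxes(boxes, nms_iou)
  # back to original image coordinates
  boxes$xmin <- boxes$xmin / prep$sx; boxes$xmax <- boxes$xmax / prep$sx
  boxes$ymin <- boxes$ymin / prep$sy; boxes$ymax <- boxes$ymax / prep$sy
  boxes[order(-boxes$score, boxes$xmin, boxes$ymin), ]
}

#' Count stomata among scored detections
#'
#' A detection counts as a stoma when its confidence score is strictly
#' greater than 0.9, which suppresses low-probability boxes in image noise.
#'
#' @param detections Box tibble with a `score` column (or a numeric score
#'   vector).
#' @param threshold Score threshold (strict inequality).
#' @return Integer count.
#' @export
count_stomata <- function(detections, threshold = 0.9) {
  if (is.data.frame(detections) && nrow(detections) == 0) return(0L)
  score <- if (is.numeric(detections)) detections else detections$score
  if (is.null(score)) abort("detections carry no scores")
  stopifnot(all(score >= 0 & score <= 1))
  sum(score > threshold)
}

#' @export
print.stomx_detector <- function(x, ...) {
  cat(sprintf("<stomx_detector> backbone %s (widths %s), %d epochs, final loss %.4f\n",
              x$cfg$backbone, paste(x$cfg$widths, collapse = "/"),
              nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' @export
glance.stomx_detector <- function(x, ...) {
  tibble(epochs = nrow(x$log), final_loss = x$log$loss[nrow(x$log)],
         backbone = x$cfg$backbone)
}

#' @export
tidy.stomx_detector <- function(x, ...) x$log

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file archives embedding the parameters, the
#' configuration and (for segmenters) the standardization statistics.
#'
#' @param model A `stomx_detector` or `stomx_seg_model`.
#' @param path Checkpoint file path.
#' @return `load_model()` returns the model; `save_model()` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("stomx_detector", "stomx_seg_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such checkpoint: ", path))
  model <- readRDS(path)
  if (!inherits(model, c("stomx_detector", "stomx_seg_model"))) {
    abort("incompatible checkpoint: not a stomx model")
  }
  model
}
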