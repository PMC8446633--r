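#' Segmenter configuration
#'
#' Training configuration for the U-Net-style epidermal cell-wall segmenter.
#' The full-scale protocol trains at 512 x 512 with batch size 8, cosine
#' annealing of the learning rate from 1e-4 to 1e-5 over 200 epochs, Kaiming
#' weight initialization and a pixelwise binary cross-entropy loss. The
#' default architecture is desk-scale (3 down/up levels, base width 16);
#' `depth`/`width` scale it up to the classic architecture.
#'
#' @param input_size `c(width, height)` the image is resized to for the
#'   network; both must be divisible by `2^depth`.
#' @param batch_size Images per gradient step.
#' @param lr_initial,lr_final Cosine-annealed learning-rate endpoints.
#' @param epochs Training epochs.
#' @param depth Number of down/up-sampling levels.
#' @param width Channels at the first level (doubling per level).
#' @param stats_mode `"dataset"` (standardization statistics over all
#'   training pixels, frozen into the model) or `"image"` (per-image).
#' @param p_affine,p_rot90 Online-augmentation probabilities.
#' @param seed Integer seed for initialization and augmentation.
#' @return Object of class `stomx_seg_config`.
#' @export
seg_config <- function(input_size = c(512, 512), batch_size = 8,
                       lr_initial = 1e-4, lr_final = 1e-5, epochs = 200,
                       depth = 3, width = 16,
                       stats_mode = c("dataset", "image"),
                       p_affine = 0.2, p_rot90 = 0.5, seed = 1L) {
  stopifnot(lr_final < lr_initial, epochs >= 1, depth >= 1, width >= 1,
            batch_size >= 1)
  if (any(input_size %% 2^depth != 0)) {
    abort("input_size must be divisible by 2^depth")
  }
  structure(
    list(input_size = as.integer(input_size), batch_size = as.integer(batch_size),
         lr_initial = lr_initial, lr_final = lr_final,
         epochs = as.integer(epochs), depth = as.integer(depth),
         width = as.integer(width), stats_mode = match.arg(stats_mode),
         p_affine = p_affine, p_rot90 = p_rot90, seed = as.integer(seed)),
    class = "stomx_seg_config"
  )
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_final + 0.5 (lr_initial - lr_final)(1 + cos(pi e / epochs))`:
#' equal to `lr_initial` at epoch 0 and `lr_final` at `epochs`, monotone
#' non-increasing in between.
#'
#' @param epoch Epoch index in `0..cfg$epochs`.
#' @param cfg Any configuration with `lr_initial`, `lr_final`, `epochs`.
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, cfg) {
  stopifnot(epoch >= 0, epoch <= cfg$epochs)
  cfg$lr_final + 0.5 * (cfg$lr_initial - cfg$lr_final) *
    (1 + cos(pi * epoch / cfg$epochs))
}

#' Fit per-channel standardization statistics
#'
#' Mean and SD of each channel over all pixels of the training images
#' (population SD). The statistics are persisted inside the trained model so
#' prediction standardizes new images identically.
#'
#' @param images List of micrographs / pixel arrays.
#' @return Object of class `stomx_standardizer` with `mu` and `sigma`
#'   (3-vectors).
#' @export
fit_standardizer <- function(images) {
  stopifnot(length(images) >= 1)
  acc_n <- 0; acc_s <- numeric(3); acc_s2 <- numeric(3)
  for (img in images) {
    px <- as_pixel_array(img)
    n <- prod(dim(px)[1:2])
    for (c in 1:3) {
      acc_s[c] <- acc_s[c] + sum(px[, , c])
      acc_s2[c] <- acc_s2[c] + sum(px[, , c]^2)
    }
    acc_n <- acc_n + n
  }
  mu <- acc_s / acc_n
  sigma <- sqrt(pmax(acc_s2 / acc_n - mu^2, 0))
  structure(list(mu = mu, sigma = sigma), class = "stomx_standardizer")
}

#' Standardize an image
#'
#' Per channel, `(I - mu) / max(sigma, 1/sqrt(N))` where `N` is the pixel
#' count of the image being standardized; the guarded divisor keeps
#' constant images finite.
#'
#' @param image Micrograph, `H x W x 3` array, or matrix (single channel,
#'   scalar statistics).
#' @param stats A [fit_standardizer()] result, or a list with `mu`, `sigma`.
#' @return Standardized array (or matrix) of the same shape.
#' @export
standardize <- function(image, stats) {
  if (is.matrix(image)) {
    n <- length(image)
    return((image - stats$mu[1]) / max(stats$sigma[1], 1 / sqrt(n)))
  }
  px <- as_pixel_array(image)
  n <- prod(dim(px)[1:2])
  out <- px
  for (c in 1:3) {
    out[, , c] <- (px[, , c] - stats$mu[c]) / max(stats$sigma[c], 1 / sqrt(n))
  }
  out
}

#' Pixelwise binary cross-entropy
#'
#' `-(1/N) sum(y log p + (1-y) log(1-p))` with predictions clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param pred Probability matrix in `[0, 1]`.
#' @param target 0/1 matrix of the same shape.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, target) {
  stopifnot(all(dim(pred) == dim(target)))
  eps <- 1e-7
  p <- clamp(pred, eps, 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# ---- parameter plumbing ------------------------------------------------

# Kaiming-initialized conv parameter pair (weight Cout x K, bias 0)
kaiming_conv <- function(c_out, k) {
  list(matrix(rnorm(c_out * k, 0, sqrt(2 / k)), c_out, k), numeric(c_out))
}

# U-Net parameter list in the order the C++ forward pass consumes it
unet_init_params <- function(depth, width, in_ch = 3) {
  ch <- width * 2^(0:depth)
  p <- list()
  add <- function(p, pr) c(p, pr)
  cin <- in_ch
  for (l in seq_len(depth)) {
    p <- add(p, kaiming_conv(ch[l], cin * 9))
    p <- add(p, kaiming_conv(ch[l], ch[l] * 9))
    cin <- ch[l]
  }
  p <- add(p, kaiming_conv(ch[depth + 1], cin * 9))
  p <- add(p, kaiming_conv(ch[depth + 1], ch[depth + 1] * 9))
  cur <- ch[depth + 1]
  for (l in rev(seq_len(depth))) {
    p <- add(p, kaiming_conv(ch[l], (cur + ch[l]) * 9))
    p <- add(p, kaiming_conv(ch[l], ch[l] * 9))
    cur <- ch[l]
  }
  p <- add(p, kaiming_conv(1, cur))
  p
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

grads_accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (i in seq_along(acc)) acc[[i]] <- acc[[i]] + g[[i]]
  acc
}

grads_scale <- function(g, s) lapply(g, function(x) x * s)

# prepare one training pair: resize to network input, standardize
seg_prepare <- function(image, mask, cfg, stats) {
  px <- as_pixel_array(image)
  w <- cfg$input_size[1]; h <- cfg$input_size[2]
  if (dim(px)[1] != h || dim(px)[2] != w) {
    px <- resize_image(px, h, w, "bilinear")
    mask <- matrix(as.integer(resize_image(mask, h, w, "nearest")), h, w)
  }
  if (cfg$stats_mode == "image") {
    stats <- list(mu = apply(px, 3, mean), sigma = apply(px, 3, sd))
  }
  list(x = standardize(px, stats), y = mask)
}

# shared training loop over prepared pairs; params may come from scratch
# init or a checkpoint (fine-tuning)
seg_train_loop <- function(params, pairs, cfg, stats, val_pairs, verbose) {
  state <- adam_init(params)
  n <- length(pairs)
  log_rows <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1, cfg)
    ord <- sample.int(n)
    losses <- numeric(0)
    bstart <- seq(1, n, by = cfg$batch_size)
    for (b in bstart) {
      idx <- ord[b:min(b + cfg$batch_size - 1, n)]
      acc <- NULL
      bl <- 0
      for (i in idx) {
        aug <- online_augment(pairs[[i]]$image, pairs[[i]]$mask,
                              p_affine = cfg$p_affine, p_rot90 = cfg$p_rot90)
        pr <- seg_prepare(aug$image, aug$mask, cfg, stats)
        st <- .cpp_unet_step(params, pr$x, pr$y, cfg$depth)
        if (!is.finite(st$loss)) {
          abort(sprintf("non-finite segmenter loss at epoch %d", epoch))
        }
        acc <- grads_accumulate(acc, st$grads)
        bl <- bl + st$loss
      }
      upd <- adam_update(params, grads_scale(acc, 1 / length(idx)), state, lr)
      params <- upd$params; state <- upd$state
      losses <- c(losses, bl / length(idx))
    }
    val_dice <- NA_real_
    if (!is.null(val_pairs)) {
      model_tmp <- list(params = params, cfg = cfg, stats = stats)
      class(model_tmp) <- "stomx_seg_model"
      ds <- vapply(val_pairs, function(p) {
        pm <- predict_mask(model_tmp, p$image)
        dice(binarize(pm, 0.5), p$mask)
      }, numeric(1))
      val_dice <- mean(ds)
    }
    log_rows[[epoch]] <- tibble(epoch = epoch, lr = lr,
                                loss = mean(losses), val_dice = val_dice)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val dice %s",
                      epoch, lr, mean(losses),
                      ifelse(is.na(val_dice), "-", sprintf("%.3f", val_dice))))
    }
  }
  list(params = params, log = dplyr::bind_rows(log_rows))
}

#' Train the cell-wall segmenter
#'
#' Seeded training of the U-Net-style segmenter on image/mask pairs with
#' online augmentation, Kaiming initialization, Adam updates under a cosine
#' learning-rate schedule and pixelwise binary cross-entropy. Standardization
#' statistics are fitted on the training images and frozen into the model.
#'
#' @param pairs List of records, each a list with `image` (micrograph or
#'   array) and `mask` (0/1 matrix).
#' @param cfg A [seg_config()].
#' @param val_pairs Optional held-out pairs; per-epoch validation Dice is
#'   logged.
#' @param verbose Print per-epoch progress.
#' @return Object of class `stomx_seg_model` with `params`, `cfg`, `stats`
#'   and a training `log` tibble.
#' @export
train_segmenter <- function(pairs, cfg = seg_config(), val_pairs = NULL,
                            verbose = FALSE) {
  if (length(pairs) == 0) abort("empty training set")
  stats <- fit_standardizer(lapply(pairs, `[[`, "image"))
  with_seed(cfg$seed, {
    params <- unet_init_params(cfg$depth, cfg$width)
    fit <- seg_train_loop(params, pairs, cfg, stats, val_pairs, verbose)
    structure(list(params = fit$params, cfg = cfg, stats = stats,
                   log = fit$log),
              class = "stomx_seg_model")
  })
}

# mirror-pad the first two dimensions of a matrix/array by p pixels
reflect_pad <- function(px, p) {
  d <- dim(px)
  ri <- c(p:1, seq_len(d[1]), d[1]:(d[1] - p + 1))
  ci <- c(p:1, seq_len(d[2]), d[2]:(d[2] - p + 1))
  if (length(d) == 2) px[ri, ci] else px[ri, ci, , drop = FALSE]
}

#' Predict a wall/intracellular probability mask
#'
#' Standardizes with the model's stored statistics, resizes to the network
#' input size, runs the segmenter under mirror-padded inference (the image
#' is reflected outward by `pad` pixels and the prediction cropped back, so
#' image borders are evaluated at interior network positions — the
#' classic remedy for zero-padding artifacts on border cells), and resizes
#' the probability map back to the original dimensions. Values are the
#' probability of the intracellular (white) class.
#'
#' @param model A trained `stomx_seg_model`.
#' @param mic Micrograph or pixel array.
#' @param pad Mirror padding in pixels (a multiple of `2^depth`).
#' @return Probability matrix in `[0, 1]` with the input's dimensions.
#' @export
predict_mask <- function(model, mic, pad = 16L) {
  stopifnot(inherits(model, "stomx_seg_model"))
  px <- as_pixel_array(mic)
  h0 <- dim(px)[1]; w0 <- dim(px)[2]
  cfg <- model$cfg
  stopifnot(pad %% 2^cfg$depth == 0)
  w <- cfg$input_size[1]; h <- cfg$input_size[2]
  if (h0 != h || w0 != w) px2 <- resize_image(px, h, w, "bilinear") else px2 <- px
  stats <- model$stats
  if (cfg$stats_mode == "image") {
    stats <- list(mu = apply(px2, 3, mean), sigma = apply(px2, 3, sd))
  }
  if (pad > 0) px2 <- reflect_pad(px2, pad)
  x <- standardize(px2, stats)
  p <- .cpp_unet_infer(model$params, x, cfg$depth)
  if (pad > 0) p <- p[(pad + 1):(pad + h), (pad + 1):(pad + w)]
  if (h0 != h || w0 != w) p <- clamp(resize_image(p, h0, w0, "bilinear"), 0, 1)
  p
}

#' Write pseudo-label masks for unlabeled images
#'
#' The semi-automatic annotation loop: a model trained on a small seed
#' subset predicts masks for the remaining images, which are written in the
#' annotation convention (0/255 PNG) for human correction.
#'
#' @param model Trained `stomx_seg_model`.
#' @param images List of micrographs (with `image_id`s) or pixel arrays.
#' @param out_dir Output directory.
#' @param threshold Binarization threshold on the probability map.
#' @return Character vector of written file paths.
#' @export
generate_pseudo_labels <- function(model, images, out_dir, threshold = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    id <- if (inherits(img, "stomx_micrograph")) img$image_id else sprintf("img_%04d", i)
    pm <- predict_mask(model, img)
    paths[i] <- file.path(out_dir, paste0(id, "_pseudo.png"))
    write_mask(binarize(pm, threshold), paths[i])
  }
  paths
}

#' Fine-tune a trained segmenter on new data
#'
#' Transfer-learning protocol: all layers are updated from the checkpoint
#' with a smaller cosine-annealed learning rate (default 5e-5 over 100
#' epochs). With `lr_initial = 0` the parameters are returned unchanged.
#'
#' @param model Trained `stomx_seg_model` (the checkpoint).
#' @param new_pairs Training pairs for the new image family.
#' @param lr_initial,epochs Fine-tuning schedule; the rate anneals to
#'   `lr_initial / 10`.
#' @param val_pairs,verbose As in [train_segmenter()].
#' @param seed Seed for the fine-tuning run.
#' @return A new `stomx_seg_model`.
#' @export
finetune_segmenter <- function(model, new_pairs, lr_initial = 5e-5,
                               epochs = 100, val_pairs = NULL,
                               verbose = FALSE, seed = 1L) {
  stopifnot(inherits(model, "stomx_seg_model"), length(new_pairs) >= 1)
  cfg <- model$cfg
  cfg$lr_initial <- lr_initial
  cfg$lr_final <- lr_initial / 10
  cfg$epochs <- as.integer(epochs)
  cfg$seed <- as.integer(seed)
  if (lr_initial == 0) {  # explicit no-op: cosine endpoints must differ
    return(structure(list(params = model$params, cfg = model$cfg,
                          stats = model$stats, log = model$log),
                     class = "stomx_seg_model"))
  }
  with_seed(cfg$seed, {
    fit <- seg_train_loop(model$params, new_pairs, cfg, model$stats,
                          val_pairs, verbose)
    structure(list(params = fit$params, cfg = cfg, stats = model$stats,
                   log = fit$log),
              class = "stomx_seg_model")
  })
}

#' @export
print.stomx_seg_model <- function(x, ...) {
  cat(sprintf("<stomx_seg_model> depth %d width %d, %d epochs, final loss %.4f\n",
              x$cfg$depth, x$cfg$width, nrow(x$log),
              x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' @export
glance.stomx_seg_model <- function(x, ...) {
  tibble(epochs = nrow(x$log), final_loss = x$log$loss[nrow(x$log)],
         final_val_dice = x$log$val_dice[nrow(x$log)],
         depth = x$cfg$depth, width = x$cfg$width)
}

#' @export
tidy.stomx_seg_model <- function(x, ...) x$log
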