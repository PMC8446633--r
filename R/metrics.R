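#' Intersection over union of two boxes
#'
#' Symmetric, in `[0, 1]`, equal to 1 only for identical boxes (half-open
#' convention, so area is `(xmax - xmin) * (ymax - ymin)`).
#'
#' @param boxA,boxB Length-4 numeric vectors `(xmin, ymin, xmax, ymax)` or
#'   one-row box tibbles.
#' @return IoU scalar.
#' @export
iou <- function(boxA, boxB) {
  to_df <- function(b) {
    if (is.data.frame(b)) return(b[1, c("xmin", "ymin", "xmax", "ymax")])
    tibble(xmin = b[1], ymin = b[2], xmax = b[3], ymax = b[4])
  }
  box_iou_matrix(to_df(boxA), to_df(boxB))[1, 1]
}

#' Average precision of a detector
#'
#' Detections (across one or many images, matched per image) are sorted by
#' decreasing score and greedily matched one-to-one to the unmatched
#' ground-truth box of highest IoU, counting a true positive when that IoU
#' strictly exceeds the threshold (default 0.6). AP is the area under the
#' all-point interpolated precision-recall curve (precision at recall `r`
#' is the maximum precision at any recall `>= r`).
#'
#' @param detections Scored box tibble; an optional `image_id` column
#'   scopes the matching per image.
#' @param truths Ground-truth box tibble (same optional `image_id`).
#' @param iou_thr IoU threshold for a true positive (strict).
#' @return Object of class `stomx_ap`: `AP`, `n_tp`, `n_fp`, `n_fn`,
#'   `iou_threshold` and the `pr` curve tibble. Zero ground truths give
#'   `AP = NA` with a warning.
#' @export
average_precision <- function(detections, truths, iou_thr = 0.6) {
  if (nrow(truths) == 0) {
    warn("average precision undefined: no ground-truth boxes")
    return(structure(list(AP = NA_real_, n_tp = 0L, n_fp = nrow(detections),
                          n_fn = 0L, iou_threshold = iou_thr,
                          pr = tibble(recall = numeric(), precision = numeric())),
                     class = "stomx_ap"))
  }
  if (!"image_id" %in% names(detections)) detections$image_id <- "img"
  if (!"image_id" %in% names(truths)) truths$image_id <- "img"
  ord <- order(-detections$score, detections$xmin, detections$ymin)
  det <- detections[ord, ]
  matched <- lapply(split(seq_len(nrow(truths)), truths$image_id),
                    function(ix) rep(FALSE, length(ix)))
  truth_by_img <- split(truths, truths$image_id)
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    tb <- truth_by_img[[det$image_id[i]]]
    if (is.null(tb) || nrow(tb) == 0) next
    ious <- box_iou_matrix(det[i, ], tb)[1, ]
    free <- !matched[[det$image_id[i]]]
    ious[!free] <- -1
    j <- which.max(ious)
    if (ious[j] > iou_thr) {
      tp[i] <- TRUE
      matched[[det$image_id[i]]][j] <- TRUE
    }
  }
  n_truth <- nrow(truths)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  # all-point interpolation: running maximum of precision from the right
  interp <- rev(cummax(rev(precision)))
  rec_pts <- c(0, recall)
  ap <- sum((rec_pts[-1] - rec_pts[-length(rec_pts)]) * interp)
  structure(
    list(AP = ap, n_tp = sum(tp), n_fp = sum(!tp),
         n_fn = n_truth - sum(tp), iou_threshold = iou_thr,
         pr = tibble(recall = recall, precision = precision,
                     interpolated = interp)),
    class = "stomx_ap")
}

#' @export
print.stomx_ap <- function(x, ...) {
  cat(sprintf("<stomx_ap> AP %.4f (IoU > %.2f): %d TP, %d FP, %d FN\n",
              x$AP, x$iou_threshold, x$n_tp, x$n_fp, x$n_fn))
  invisible(x)
}

#' Dice coefficient of two binary masks
#'
#' `2 TP / (2 TP + FP + FN)` over pixels of the positive (1) class;
#' symmetric, in `[0, 1]`, 1 only when the masks agree. Two empty masks
#' are identical and score 1.
#'
#' @param pred_mask,true_mask 0/1 matrices of the same shape.
#' @return Dice scalar.
#' @export
dice <- function(pred_mask, true_mask) {
  stopifnot(all(dim(pred_mask) == dim(true_mask)))
  tp <- sum(pred_mask == 1 & true_mask == 1)
  fp <- sum(pred_mask == 1 & true_mask == 0)
  fn <- sum(pred_mask == 0 & true_mask == 1)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Counting accuracy
#'
#' `1 - |automatic - manual| / manual`; can fall below 0 for gross
#' overcounts. Undefined (`NA`, with a warning) when the manual count is 0.
#'
#' @param automatic,manual Count vectors.
#' @return Accuracy vector.
#' @export
counting_accuracy <- function(automatic, manual) {
  n <- max(length(automatic), length(manual))
  automatic <- rep_len(automatic, n)
  manual <- rep_len(manual, n)
  out <- ifelse(manual > 0, 1 - abs(automatic - manual) / manual, NA_real_)
  if (anyNA(out)) warn("counting accuracy undefined where the manual count is 0")
  out
}

#' Counting precision
#'
#' `log10(manual / automatic)`: negative values flag overcounting, positive
#' values undercounting, 0 exact agreement. Undefined (`NA`, warned) when
#' either count is 0.
#'
#' @param manual,automatic Count vectors.
#' @param base Logarithm base (10 by default; `exp(1)` for natural log).
#' @return Precision vector.
#' @export
counting_precision <- function(manual, automatic, base = 10) {
  n <- max(length(automatic), length(manual))
  automatic <- rep_len(automatic, n)
  manual <- rep_len(manual, n)
  out <- ifelse(manual > 0 & automatic > 0,
                log(manual / automatic, base = base), NA_real_)
  if (anyNA(out)) warn("counting precision undefined where a count is 0")
  out
}

#' Stomatal-index accuracy and precision
#'
#' The counting accuracy/precision functional forms applied to stomatal
#' index values instead of raw counts.
#'
#' @param auto_idx,manual_idx Index values (percent).
#' @param base Logarithm base for the precision.
#' @return Numeric vector.
#' @export
index_accuracy <- function(auto_idx, manual_idx) {
  counting_accuracy(auto_idx, manual_idx)
}

#' @rdname index_accuracy
#' @export
index_precision <- function(manual_idx, auto_idx, base = 10) {
  counting_precision(manual_idx, auto_idx, base = base)
}

#' Agreement with the identity line
#'
#' Manual-vs-automatic agreement summarized against the line `y = x`:
#' `R^2 = 1 - sum((x - y)^2) / sum((x - mean(x))^2)` (residuals about the
#' identity line over total sum of squares of the manual values) and
#' `RMSE = sqrt(mean((x - y)^2))`.
#'
#' @param manual,automatic Numeric vectors (length >= 2).
#' @return Object of class `stomx_identity_fit` with `r2`, `rmse`, `n` and
#'   the data; supports [generics::tidy()], [generics::glance()] and
#'   `autoplot()`.
#' @export
identity_regression <- function(manual, automatic) {
  stopifnot(length(manual) == length(automatic), length(manual) >= 2)
  ss_res <- sum((manual - automatic)^2)
  ss_tot <- sum((manual - mean(manual))^2)
  structure(
    list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / length(manual)),
         n = length(manual), manual = manual, automatic = automatic),
    class = "stomx_identity_fit")
}

#' @export
print.stomx_identity_fit <- function(x, ...) {
  cat(sprintf("<stomx_identity_fit> n %d  R2 %.4f  RMSE %.4f\n",
              x$n, x$r2, x$rmse))
  invisible(x)
}

#' @export
tidy.stomx_identity_fit <- function(x, ...) {
  tibble(manual = x$manual, automatic = x$automatic,
         residual = x$automatic - x$manual)
}

#' @export
glance.stomx_identity_fit <- function(x, ...) {
  tibble(r.squared = x$r2, rmse = x$rmse, n = x$n)
}

#' Coefficient of variation
#'
#' `sd(x) / mean(x)` — the dispersion measure used to compare the
#' within-cultivar stability of the stomatal index against stomatal
#' density.
#'
#' @param x Numeric vector.
#' @return CV scalar.
#' @export
cv <- function(x) sd(x) / mean(x)

#' Summarize counting performance per trait
#'
#' For a table of per-image manual/automatic counts (long format with a
#' `trait` column), computes the counting accuracy and precision per image
#' and reports min/max/mean/SD of each, the coefficient of variation of
#' the automatic counts, the Pearson correlation, and identity-line
#' `R^2`/RMSE — the layout of the study's per-trait report tables.
#'
#' @param records Tibble with columns `trait`, `manual`, `automatic`.
#' @param base Logarithm base for precisions.
#' @return One row per trait.
#' @export
summarize_counts <- function(records, base = 10) {
  stopifnot(nrow(records) >= 1,
            all(c("trait", "manual", "automatic") %in% names(records)))
  records |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      acc <- suppressWarnings(counting_accuracy(d$automatic, d$manual))
      prec <- suppressWarnings(counting_precision(d$manual, d$automatic, base))
      fit <- identity_regression(d$manual, d$automatic)
      stat <- function(f, x) if (any(!is.na(x))) f(x[!is.na(x)]) else NA_real_
      tibble(
        n = nrow(d),
        accuracy_min = stat(min, acc),
        accuracy_max = stat(max, acc),
        accuracy_mean = stat(mean, acc),
        accuracy_sd = stat(sd, acc),
        precision_min = stat(min, prec),
        precision_max = stat(max, prec),
        precision_mean = stat(mean, prec),
        precision_sd = stat(sd, prec),
        cv_automatic = cv(d$automatic),
        pearson_r = suppressWarnings(cor(d$manual, d$automatic)),
        r2 = fit$r2, rmse = fit$rmse)
    }) |>
    dplyr::ungroup()
}

#' Paired comparison of index values between magnifications
#'
#' Two-sided paired t-test (df = n - 1) between per-leaf stomatal-index
#' values measured at two magnifications, plus their Pearson correlation.
#' Zero-variance differences are flagged (`NA` statistics with a warning)
#' rather than reported as significant.
#'
#' @param values_a,values_b Paired numeric vectors.
#' @return One-row tibble: `mean_a`, `mean_b`, `statistic`, `df`,
#'   `p_value`, `pearson_r`.
#' @export
compare_magnifications <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  r <- suppressWarnings(cor(values_a, values_b))
  d <- values_a - values_b
  if (sd(d) == 0) {
    warn("paired t-test undefined: zero-variance differences")
    return(tibble(mean_a = mean(values_a), mean_b = mean(values_b),
                  statistic = NA_real_, df = length(d) - 1,
                  p_value = NA_real_, pearson_r = r))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  tibble(mean_a = mean(values_a), mean_b = mean(values_b),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, pearson_r = r)
}

#' Average running time per image
#'
#' `ART = (T_stoma + T_cell + T_SI) / N`: total stage wall times over the
#' number of images. Hardware-dependent; reported, never asserted.
#'
#' @param timings List with `T_stoma`, `T_cell`, `T_SI`, `N`, or a
#'   [run_pipeline()] result carrying a `"timing"` attribute.
#' @return One-row tibble: stage totals, `N`, `ART` seconds/image.
#' @export
measure_art <- function(timings) {
  if (inherits(timings, "stomx_counts")) timings <- attr(timings, "timing")
  stopifnot(is.list(timings), !is.null(timings$N))
  if (timings$N == 0) abort("ART undefined for zero images")
  tibble(T_stoma = timings$T_stoma, T_cell = timings$T_cell,
         T_SI = timings$T_SI, N = timings$N,
         ART = (timings$T_stoma + timings$T_cell + timings$T_SI) / timings$N)
}
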