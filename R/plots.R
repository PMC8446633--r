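#' Plot a micrograph with optional boxes
#'
#' Renders the pixel grid with ggplot2 and overlays stoma boxes (ground
#' truth or scored detections).
#'
#' @param mic A [micrograph()].
#' @param boxes Optional box tibble.
#' @param box_colour Box outline colour.
#' @return A ggplot object.
#' @export
plot_micrograph <- function(mic, boxes = NULL, box_colour = "red") {
  px <- as_pixel_array(mic)
  H <- dim(px)[1]; W <- dim(px)[2]
  df <- tibble(
    x = rep(seq_len(W) - 0.5, each = H),
    y = rep(seq_len(H) - 0.5, times = W),
    fill = grDevices::rgb(px[, , 1] / 255, px[, , 2] / 255, px[, , 3] / 255))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(boxes) && nrow(boxes)) {
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, colour = box_colour, fill = NA, linewidth = 0.4)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Precision-recall curve of a detector evaluation
#'
#' @param object An [average_precision()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stomx_ap <- function(object, ...) {
  ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$precision), colour = "grey60") +
    ggplot2::geom_step(ggplot2::aes(y = .data$interpolated), colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("AP = %.3f (IoU > %.2f)",
                                  object$AP, object$iou_threshold)) +
    ggplot2::theme_minimal()
}

#' Manual-vs-automatic agreement plot
#'
#' Scatter of automatic against manual values with the identity line.
#'
#' @param object An [identity_regression()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stomx_identity_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$manual, y = .data$automatic)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50",
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Manual", y = "Automatic",
                  title = sprintf("R² = %.3f, RMSE = %.3f",
                                  object$r2, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Training-log curve of a model
#'
#' Loss (and validation Dice, when logged) across epochs.
#'
#' @param object A `stomx_seg_model` or `stomx_detector`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stomx_seg_model <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss), colour = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.stomx_seg_model
#' @export
autoplot.stomx_detector <- autoplot.stomx_seg_model
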