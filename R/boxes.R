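#' Construct a table of stoma bounding boxes
#'
#' Boxes use the package's internal convention: 0-based, half-open pixel
#' intervals `[xmin, xmax) x [ymin, ymax)`, so `xmax - xmin` is the box width
#' in pixels. Ground-truth boxes carry no `score`; detections carry a
#' confidence score in `[0, 1]`.
#'
#' @param xmin,ymin,xmax,ymax Numeric coordinate vectors.
#' @param score Optional numeric vector of confidences in `[0, 1]`.
#' @return A tibble with one row per box.
#' @export
stoma_boxes <- function(xmin = numeric(), ymin = numeric(),
                        xmax = numeric(), ymax = numeric(), score = NULL) {
  if (length(xmin) && any(xmin >= xmax | ymin >= ymax)) {
    abort("invalid box: requires xmin < xmax and ymin < ymax")
  }
  out <- tibble(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (!is.null(score)) {
    if (length(score) && (min(score) < 0 || max(score) > 1)) {
      abort("box scores must lie in [0, 1]")
    }
    out$score <- as.numeric(score)
  }
  out
}

#' Clip boxes to image bounds
#'
#' @param boxes A box tibble (see [stoma_boxes()]).
#' @param width,height Image dimensions in pixels.
#' @param drop_empty Drop boxes with no remaining area.
#' @return The clipped box tibble.
#' @export
clip_boxes <- function(boxes, width, height, drop_empty = TRUE) {
  if (nrow(boxes) == 0) return(boxes)
  boxes$xmin <- clamp(boxes$xmin, 0, width)
  boxes$xmax <- clamp(boxes$xmax, 0, width)
  boxes$ymin <- clamp(boxes$ymin, 0, height)
  boxes$ymax <- clamp(boxes$ymax, 0, height)
  if (drop_empty) boxes <- boxes[boxes$xmax > boxes$xmin & boxes$ymax > boxes$ymin, ]
  boxes
}

#' Half-at-edge visibility rule
#'
#' An annotation convention for objects straddling the image border: a stoma
#' is kept when more than half of its length (the longer box side) lies
#' inside the image, and it overlaps the image at all in the other direction.
#'
#' @param boxes Box tibble, possibly extending beyond the canvas.
#' @param width,height Canvas size in pixels.
#' @return Logical vector, one entry per box.
#' @export
box_visible <- function(boxes, width, height) {
  if (nrow(boxes) == 0) return(logical(0))
  in_x <- pmin(boxes$xmax, width) - pmax(boxes$xmin, 0)
  in_y <- pmin(boxes$ymax, height) - pmax(boxes$ymin, 0)
  len_x <- boxes$xmax - boxes$xmin
  len_y <- boxes$ymax - boxes$ymin
  major_frac <- ifelse(len_x >= len_y, in_x / len_x, in_y / len_y)
  minor_in <- ifelse(len_x >= len_y, in_y, in_x)
  major_frac > 0.5 & minor_in > 0
}

# internal: IoU matrix between two box sets (matrices/data frames with
# xmin, ymin, xmax, ymax), half-open convention so area = (xmax-xmin)*(ymax-ymin)
box_iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  if (na == 0 || nb == 0) return(out)
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  for (j in seq_len(nb)) {
    iw <- pmax(0, pmin(a$xmax, b$xmax[j]) - pmax(a$xmin, b$xmin[j]))
    ih <- pmax(0, pmin(a$ymax, b$ymax[j]) - pmax(a$ymin, b$ymin[j]))
    inter <- iw * ih
    out[, j] <- inter / (area_a + area_b[j] - inter)
  }
  out
}
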