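#' Resize an image, mask or probability map
#'
#' Interpolating resize with pixel-center alignment. Images are typically
#' resized with `"bilinear"` or `"cubic"` interpolation; binary masks must use
#' `"nearest"` so that no intermediate values appear.
#'
#' @param x Matrix, `H x W x C` array, or [micrograph()].
#' @param height,width Output size in pixels.
#' @param method `"nearest"`, `"bilinear"` or `"cubic"` (Keys cubic
#'   convolution, a = -0.5).
#' @return Same container type as `x`, resized.
#' @export
resize_image <- function(x, height, width,
                         method = c("bilinear", "nearest", "cubic")) {
  method <- match.arg(method)
  mcode <- match(method, c("nearest", "bilinear", "cubic")) - 1L
  if (inherits(x, "stomx_micrograph")) {
    px <- resize_image(x$pixels, height, width, method)
    return(micrograph(clamp(round(px), 0, 255), x$magnification, x$image_id))
  }
  if (is.matrix(x)) {
    return(.cpp_resize_mat(x, as.integer(height), as.integer(width), mcode))
  }
  out <- array(0, dim = c(height, width, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) {
    out[, , c] <- .cpp_resize_mat(x[, , c], as.integer(height),
                                  as.integer(width), mcode)
  }
  out
}

# internal: inverse-mapped affine warp of a matrix/array.
# minv maps output (x, y) pixel coordinates to source coordinates.
warp_affine <- function(x, minv, height, width,
                        method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  mcode <- match(method, c("nearest", "bilinear")) - 1L
  if (is.matrix(x)) {
    return(.cpp_warp_affine_mat(x, minv, as.integer(height),
                                as.integer(width), mcode, fill))
  }
  out <- array(0, dim = c(height, width, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) {
    out[, , c] <- .cpp_warp_affine_mat(x[, , c], minv, as.integer(height),
                                       as.integer(width), mcode, fill)
  }
  out
}
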