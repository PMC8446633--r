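#' Construct a micrograph object
#'
#' A micrograph is an 8-bit RGB pixel grid with a magnification tag and an
#' identifier. Pixels are stored as an `H x W x 3` numeric array with values
#' in `[0, 255]`; row index is the image y coordinate (top to bottom), column
#' index the x coordinate.
#'
#' @param pixels Numeric array `H x W x 3` (or an `H x W` matrix, replicated
#'   across channels) with intensities in `[0, 255]`.
#' @param magnification One of `"x10"`, `"x20"`, `"unknown"`.
#' @param image_id Character identifier.
#' @return An object of class `stomx_micrograph`.
#' @export
micrograph <- function(pixels, magnification = "unknown", image_id = "img") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (dim(pixels)[1] < 64 || dim(pixels)[2] < 64) {
    abort("micrograph must be at least 64 x 64 pixels")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("micrograph intensities must lie in [0, 255]")
  }
  magnification <- match.arg(magnification, c("x10", "x20", "unknown"))
  structure(
    list(pixels = pixels, magnification = magnification,
         image_id = as.character(image_id)),
    class = "stomx_micrograph"
  )
}

#' @export
print.stomx_micrograph <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stomx_micrograph> %s  %d x %d px  magnification %s\n",
              x$image_id, d[2], d[1], x$magnification))
  invisible(x)
}

#' @export
dim.stomx_micrograph <- function(x) dim(x$pixels)

#' Read / write a micrograph as PNG
#'
#' @param path PNG file path.
#' @param magnification,image_id Metadata attached on read (the id defaults
#'   to the file name).
#' @return `read_micrograph()` returns a [micrograph()]; `write_micrograph()`
#'   returns `path` invisibly.
#' @export
read_micrograph <- function(path, magnification = "unknown", image_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such image file: ", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  px <- px[, , 1:3, drop = FALSE] * 255
  micrograph(round(px), magnification,
             image_id %||% sub("\\.png$", "", basename(path)))
}

#' @rdname read_micrograph
#' @param x A [micrograph()].
#' @export
write_micrograph <- function(x, path) {
  stopifnot(inherits(x, "stomx_micrograph"))
  png::writePNG(x$pixels / 255, path)
  invisible(path)
}

# internal: accept a micrograph, array or matrix and return an HxWx3 array
as_pixel_array <- function(x) {
  if (inherits(x, "stomx_micrograph")) return(x$pixels)
  if (is.matrix(x)) return(array(rep(x, 3), dim = c(dim(x), 3)))
  stopifnot(length(dim(x)) == 3)
  x
}
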