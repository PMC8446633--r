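#' Read and write Pascal VOC box annotations
#'
#' VOC XML files store 1-based inclusive pixel coordinates; in memory the
#' package uses 0-based half-open boxes, so a VOC box `(1, 1, 10, 10)` reads
#' as `(0, 0, 10, 10)`. The round trip is lossless for integer coordinates.
#'
#' @param xml_path Path to the XML file.
#' @return `read_voc()` returns a box tibble (see [stoma_boxes()]).
#' @export
read_voc <- function(xml_path) {
  if (!file.exists(xml_path)) abort(paste0("no such annotation file: ", xml_path))
  doc <- xml2::read_xml(xml_path)
  objs <- xml2::xml_find_all(doc, ".//object")
  get_num <- function(node, what) {
    v <- xml2::xml_find_first(node, paste0(".//", what))
    if (is.na(v)) abort(sprintf("malformed VOC XML: missing <%s> in %s",
                                what, xml_path))
    as.numeric(xml2::xml_text(v))
  }
  xmin <- vapply(objs, get_num, numeric(1), what = "xmin") - 1
  ymin <- vapply(objs, get_num, numeric(1), what = "ymin") - 1
  xmax <- vapply(objs, get_num, numeric(1), what = "xmax")
  ymax <- vapply(objs, get_num, numeric(1), what = "ymax")
  if (length(xmin) && any(xmin >= xmax | ymin >= ymax)) {
    abort(sprintf("malformed VOC XML: degenerate <bndbox> in %s", xml_path))
  }
  stoma_boxes(xmin, ymin, xmax, ymax)
}

#' @rdname read_voc
#' @param boxes Box tibble in the in-memory convention.
#' @param image_meta List with `filename`, `width`, `height` for the XML header.
#' @export
write_voc <- function(boxes, image_meta, xml_path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", image_meta$filename %||% "image")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image_meta$width))
  xml2::xml_add_child(size, "height", as.character(image_meta$height))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(boxes))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", "stoma")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(boxes$xmin[i] + 1))
    xml2::xml_add_child(bb, "ymin", as.character(boxes$ymin[i] + 1))
    xml2::xml_add_child(bb, "xmax", as.character(boxes$xmax[i]))
    xml2::xml_add_child(bb, "ymax", as.character(boxes$ymax[i]))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Read and write binary wall masks
#'
#' Masks follow the annotation convention: black (0) marks cell walls, leaf
#' veins and subsidiary cells; white (255) marks intracellular regions and
#' trichomes. In memory a mask is an integer matrix of 0 (wall) and 1
#' (intracellular). On read, 8-bit values `<= 127` map to wall and `> 127`
#' to intracellular; on write, 0/255 are emitted.
#'
#' @param png_path PNG path.
#' @return `read_mask()` returns a 0/1 integer matrix.
#' @export
read_mask <- function(png_path) {
  if (!file.exists(png_path)) abort(paste0("no such mask file: ", png_path))
  px <- png::readPNG(png_path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  if (length(px) == 0) abort(paste0("empty mask image: ", png_path))
  mask <- matrix(as.integer(round(px * 255) > 127), nrow(px), ncol(px))
  mask
}

#' @rdname read_mask
#' @param mask 0/1 integer matrix.
#' @export
write_mask <- function(mask, png_path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), png_path)
  invisible(png_path)
}

#' Split image ids into cross-validation folds
#'
#' Deterministic (seeded) partition into `k` mutually exclusive folds whose
#' sizes differ by at most one image.
#'
#' @param image_ids Character vector of ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble with columns `image_id` and `fold` (1..k).
#' @export
make_folds <- function(image_ids, k = 5, seed = 1L) {
  stopifnot(length(image_ids) >= k, k >= 2)
  with_seed(seed, {
    shuffled <- sample(image_ids)
    tibble(image_id = shuffled,
           fold = rep(seq_len(k), length.out = length(shuffled)))
  })
}

# internal: rotate an annotated record by an exact multiple of 90 degrees
# (clockwise); canvas dimensions swap for 90/270.
rot90_mat <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

rotate_exact <- function(pixels, boxes, mask, quarter_turns) {
  q <- quarter_turns %% 4
  for (i in seq_len(q)) {
    H <- dim(pixels)[1]
    if (is.matrix(pixels)) pixels <- rot90_mat(pixels) else {
      pixels <- array(apply(pixels, 3, rot90_mat),
                      dim = c(dim(pixels)[2], dim(pixels)[1], dim(pixels)[3]))
    }
    if (!is.null(mask)) mask <- rot90_mat(mask)
    if (!is.null(boxes) && nrow(boxes)) {
      sc <- if ("score" %in% names(boxes)) boxes$score else NULL
      boxes <- stoma_boxes(xmin = H - boxes$ymax, ymin = boxes$xmin,
                           xmax = H - boxes$ymin, ymax = boxes$xmax,
                           score = sc)
    }
  }
  list(pixels = pixels, boxes = boxes, mask = mask)
}

#' Rotate an annotated micrograph
#'
#' Multiples of 90 degrees rotate the pixel grid exactly (a bijection of
#' pixels; clockwise). Other angles expand the canvas to circumscribe the
#' rotated image, fill the background white, resample bilinearly (masks:
#' nearest) and replace each box by the axis-aligned circumscribed rectangle
#' of its rotated corners.
#'
#' @param mic A [micrograph()].
#' @param boxes Optional box tibble.
#' @param mask Optional 0/1 mask matrix.
#' @param angle Rotation angle in degrees, clockwise.
#' @return List with `micrograph`, `boxes`, `mask`.
#' @export
rotate_annotated <- function(mic, boxes = NULL, mask = NULL, angle) {
  stopifnot(inherits(mic, "stomx_micrograph"))
  px <- mic$pixels
  if (angle %% 90 == 0) {
    r <- rotate_exact(px, boxes, mask, angle %/% 90)
    out_mic <- micrograph(r$pixels, mic$magnification,
                          paste0(mic$image_id, "_rot", angle %% 360))
    return(list(micrograph = out_mic, boxes = r$boxes, mask = r$mask))
  }
  H <- dim(px)[1]; W <- dim(px)[2]
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  W2 <- ceiling(W * abs(ct) + H * abs(st))
  H2 <- ceiling(W * abs(st) + H * abs(ct))
  # forward map: p' = R (p - c) + c'; sampling uses the inverse
  cxy <- c((W - 1) / 2, (H - 1) / 2)
  cxy2 <- c((W2 - 1) / 2, (H2 - 1) / 2)
  rot <- matrix(c(ct, st, -st, ct), 2, 2)       # clockwise in image coords
  minv <- cbind(t(rot), cxy - t(rot) %*% cxy2)  # R^T (p' - c') + c
  out_px <- clamp(round(warp_affine(px, minv, H2, W2, "bilinear", fill = 255)),
                  0, 255)
  out_mask <- if (!is.null(mask)) {
    matrix(as.integer(warp_affine(mask, minv, H2, W2, "nearest", fill = 1)),
           H2, W2)
  }
  out_boxes <- NULL
  if (!is.null(boxes)) {
    out_boxes <- boxes
    if (nrow(boxes)) {
      fwd <- function(x, y) rot %*% (c(x, y) - cxy) + cxy2
      for (i in seq_len(nrow(boxes))) {
        cs <- cbind(fwd(boxes$xmin[i], boxes$ymin[i]),
                    fwd(boxes$xmax[i], boxes$ymin[i]),
                    fwd(boxes$xmin[i], boxes$ymax[i]),
                    fwd(boxes$xmax[i], boxes$ymax[i]))
        out_boxes$xmin[i] <- min(cs[1, ]); out_boxes$xmax[i] <- max(cs[1, ])
        out_boxes$ymin[i] <- min(cs[2, ]); out_boxes$ymax[i] <- max(cs[2, ])
      }
      out_boxes <- clip_boxes(out_boxes, W2, H2)
    }
  }
  out_mic <- micrograph(out_px, mic$magnification,
                        paste0(mic$image_id, "_rot", angle))
  list(micrograph = out_mic, boxes = out_boxes, mask = out_mask)
}

#' Offline augmentation: originals plus 45/90/135-degree rotations
#'
#' The detector-training protocol keeps each original image and adds copies
#' rotated by 45, 90 and 135 degrees with their boxes transformed, so the
#' set size quadruples.
#'
#' @param records List of records, each a list with `micrograph` and `boxes`
#'   (optionally `mask`).
#' @param angles Rotation angles in degrees.
#' @return List of `length(records) * (1 + length(angles))` records.
#' @export
offline_augment <- function(records, angles = c(45, 90, 135)) {
  out <- list()
  for (rec in records) {
    out[[length(out) + 1]] <- rec
    for (a in angles) {
      r <- rotate_annotated(rec$micrograph, rec$boxes, rec$mask, a)
      out[[length(out) + 1]] <- list(micrograph = r$micrograph,
                                     boxes = r$boxes, mask = r$mask)
    }
  }
  out
}

#' Online augmentation for segmentation pairs
#'
#' Applies, with probability `p_affine` (default 0.2), a small random affine
#' perturbation, and with probability `p_rot90` (default 0.5) a 90-degree
#' rotation — identically to the image and its mask. Draws come from the
#' session RNG, so a seeded caller gets reproducible augmentation.
#'
#' @param image `H x W x 3` pixel array or [micrograph()].
#' @param mask 0/1 integer matrix of the same height/width.
#' @param p_affine,p_rot90 Transform probabilities.
#' @param max_rot,max_shear Maximal affine rotation/shear in degrees.
#' @param max_scale,max_trans Maximal relative scale change / translation.
#' @return List with transformed `image` (array) and `mask`.
#' @export
online_augment <- function(image, mask, p_affine = 0.2, p_rot90 = 0.5,
                           max_rot = 10, max_shear = 10, max_scale = 0.05,
                           max_trans = 0.05) {
  px <- as_pixel_array(image)
  stopifnot(dim(px)[1] == nrow(mask), dim(px)[2] == ncol(mask))
  applied <- c(affine = FALSE, rot90 = FALSE)
  if (runif(1) < p_affine) {
    applied[["affine"]] <- TRUE
    H <- dim(px)[1]; W <- dim(px)[2]
    th <- runif(1, -max_rot, max_rot) * pi / 180
    sh <- runif(1, -max_shear, max_shear) * pi / 180
    sc <- 1 + runif(1, -max_scale, max_scale)
    tx <- runif(1, -max_trans, max_trans) * W
    ty <- runif(1, -max_trans, max_trans) * H
    rot <- sc * matrix(c(cos(th), sin(th), -sin(th) + tan(sh), cos(th)), 2, 2)
    cxy <- c((W - 1) / 2, (H - 1) / 2)
    fwd_off <- cxy + c(tx, ty) - rot %*% cxy
    rinv <- solve(rot)
    minv <- cbind(rinv, -rinv %*% fwd_off)
    px <- clamp(round(warp_affine(px, minv, H, W, "bilinear", fill = 255)), 0, 255)
    mask <- matrix(as.integer(warp_affine(mask, minv, H, W, "nearest", fill = 1)),
                   H, W)
  }
  if (runif(1) < p_rot90) {
    applied[["rot90"]] <- TRUE
    r <- rotate_exact(px, NULL, mask, 1)
    px <- r$pixels; mask <- r$mask
  }
  structure(list(image = px, mask = mask), applied = applied)
}

#' Simulate higher-magnification acquisition
#'
#' Reproduces the x20 acquisition protocol: crop a window (default
#' 680 x 512, top-left corner unless `corner = "random"`), enlarge it with
#' cubic interpolation by `scale` (default 2), carry boxes and mask along,
#' and retag the magnification. Boxes that fail the half-at-edge visibility
#' rule inside the crop window are dropped.
#'
#' @param mic A [micrograph()] at least as large as the crop window.
#' @param boxes Optional box tibble.
#' @param mask Optional 0/1 mask.
#' @param crop_w,crop_h Crop window size in pixels.
#' @param corner `"topleft"` or `"random"` (seeded by the session RNG).
#' @param scale Integer enlargement factor.
#' @return List with `micrograph` (tagged `"x20"`), `boxes`, `mask`.
#' @export
simulate_20x <- function(mic, boxes = NULL, mask = NULL, crop_w = 680,
                         crop_h = 512, corner = c("topleft", "random"),
                         scale = 2) {
  stopifnot(inherits(mic, "stomx_micrograph"))
  corner <- match.arg(corner)
  H <- dim(mic$pixels)[1]; W <- dim(mic$pixels)[2]
  if (W < crop_w || H < crop_h) {
    abort(sprintf("image %dx%d smaller than %dx%d crop window",
                  W, H, crop_w, crop_h))
  }
  ox <- 0L; oy <- 0L
  if (corner == "random") {
    ox <- sample.int(W - crop_w + 1L, 1) - 1L
    oy <- sample.int(H - crop_h + 1L, 1) - 1L
  }
  px <- mic$pixels[(oy + 1):(oy + crop_h), (ox + 1):(ox + crop_w), , drop = FALSE]
  px <- clamp(round(resize_image(px, crop_h * scale, crop_w * scale, "cubic")),
              0, 255)
  out_mask <- NULL
  if (!is.null(mask)) {
    m <- mask[(oy + 1):(oy + crop_h), (ox + 1):(ox + crop_w), drop = FALSE]
    out_mask <- matrix(as.integer(resize_image(m, crop_h * scale,
                                               crop_w * scale, "nearest")),
                       crop_h * scale, crop_w * scale)
  }
  out_boxes <- NULL
  if (!is.null(boxes)) {
    b <- boxes
    if (nrow(b)) {
      b$xmin <- b$xmin - ox; b$xmax <- b$xmax - ox
      b$ymin <- b$ymin - oy; b$ymax <- b$ymax - oy
      b <- b[box_visible(b, crop_w, crop_h), , drop = FALSE]
      b <- clip_boxes(b, crop_w, crop_h)
      b$xmin <- b$xmin * scale; b$xmax <- b$xmax * scale
      b$ymin <- b$ymin * scale; b$ymax <- b$ymax * scale
    }
    out_boxes <- b
  }
  out_mic <- micrograph(px, "x20", paste0(mic$image_id, "_x20"))
  list(micrograph = out_mic, boxes = out_boxes, mask = out_mask)
}
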