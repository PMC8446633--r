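#' Specify a synthetic leaf-epidermis scene
#'
#' The synthetic generator emulates micrographs of a grass-type leaf
#' epidermis: tightly packed elongated pavement cells separated by darker
#' cell walls, a controllable fraction of cells replaced by stomata (a dark
#' dumbbell-shaped guard-cell pair, optionally flanked by subsidiary cells
#' drawn in wall tone), occasional bright trichomes, a mild illumination
#' gradient and Gaussian intensity noise. Every scene comes with exact ground
#' truth: stoma bounding boxes, a binary cell-wall mask and counts.
#'
#' @param width_px,height_px Canvas size in pixels (at least 64).
#' @param cell_elongation Major/minor axis ratio of a typical cell (>= 1);
#'   cells stretch along the x axis.
#' @param target_cell_count Approximate number of tessellation regions.
#' @param target_stomatal_index_pct Target stomatal index in percent,
#'   strictly between 0 and 100; the realized index varies with seed and
#'   edge effects.
#' @param subsidiary_cells Render subsidiary cells flanking each stoma in
#'   wall tone (they are never counted as epidermal cells).
#' @param trichome_rate Expected number of trichomes per image (Poisson).
#' @param noise_sigma SD of additive Gaussian intensity noise (8-bit units).
#' @param wall_thickness_px Cell-wall thickness in pixels.
#' @param seed Integer seed; identical specs reproduce bit-identical scenes.
#' @return An object of class `stomx_scene_spec`.
#' @export
scene_spec <- function(width_px = 256, height_px = 256, cell_elongation = 3,
                       target_cell_count = 48, target_stomatal_index_pct = 15,
                       subsidiary_cells = TRUE, trichome_rate = 0.5,
                       noise_sigma = 8, wall_thickness_px = 3, seed = 1L) {
  stopifnot(width_px >= 64, height_px >= 64, cell_elongation >= 1,
            target_cell_count >= 1, noise_sigma >= 0, trichome_rate >= 0,
            wall_thickness_px >= 1)
  if (!(target_stomatal_index_pct > 0 && target_stomatal_index_pct < 100)) {
    abort("target_stomatal_index_pct must lie strictly between 0 and 100")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         cell_elongation = cell_elongation,
         target_cell_count = as.integer(target_cell_count),
         target_stomatal_index_pct = target_stomatal_index_pct,
         subsidiary_cells = isTRUE(subsidiary_cells),
         trichome_rate = trichome_rate, noise_sigma = noise_sigma,
         wall_thickness_px = as.integer(wall_thickness_px),
         seed = as.integer(seed)),
    class = "stomx_scene_spec"
  )
}

#' Generate one synthetic scene with exact ground truth
#'
#' Renders the scene described by a [scene_spec()]: a seeded anisotropic
#' point process is partitioned by nearest-seed assignment (axis-scaled so
#' cells elongate), region boundaries become walls, a seeded subset of
#' regions becomes stomata, and intensity noise is added last. The truth
#' record is derived from the rendered wall mask itself (epidermal cells =
#' white connected domains) and from the placed stomata (boxes kept by the
#' half-at-edge visibility rule), so it is exact by construction and
#' unaffected by noise.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `micrograph` (a [micrograph()]) and `truth`
#'   (class `stomx_scene_truth`: `stoma_boxes`, `wall_mask`, `n_stomata`,
#'   `n_epidermal_cells`, `stomatal_index_pct`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "stomx_scene_spec"))
  W <- spec$width_px; H <- spec$height_px
  e <- spec$cell_elongation; N <- spec$target_cell_count
  wt <- spec$wall_thickness_px

  # jittered anisotropic grid of seeds
  area <- W * H / N
  wy <- sqrt(area / e)
  n_rows <- max(1L, as.integer(round(H / wy)))
  n_cols <- max(1L, as.integer(round(N / n_rows)))
  pitch_x <- W / n_cols; pitch_y <- H / n_rows
  if (pitch_x < max(8, 3 * wt) || pitch_y < max(6, 2 * wt + 2)) {
    abort(sprintf(
      "unsatisfiable scene: %d cells of elongation %.1f do not fit a %dx%d canvas",
      N, e, W, H), class = "stomx_generation_error")
  }
  n_act <- n_rows * n_cols

  with_seed(spec$seed, {
    cx <- rep((seq_len(n_cols) - 0.5) * pitch_x, each = n_rows) +
      runif(n_act, -0.3, 0.3) * pitch_x
    cy <- rep((seq_len(n_rows) - 0.5) * pitch_y, times = n_cols) +
      runif(n_act, -0.3, 0.3) * pitch_y
    vor <- .cpp_voronoi_scene(H, W, cx, cy, e, max(1L, wt %/% 2L))
    region <- vor$region
    wall <- vor$wall

    # which regions become stomata
    n_sto <- round(spec$target_stomatal_index_pct / 100 * n_act)
    sto_idx <- if (n_sto > 0) sort(sample.int(n_act, n_sto)) else integer(0)

    XX <- matrix(rep(0:(W - 1), each = H), H, W)
    YY <- matrix(rep(0:(H - 1), W), H, W)

    interior_col <- clamp(190 + rnorm(n_act, 0, 8), 165, 215)
    img <- matrix(interior_col[region], H, W)
    img[wall] <- 70

    mask <- matrix(1L, H, W)
    mask[wall] <- 0L

    # stomata: dumbbell guard-cell pair along the cell's long axis
    rr <- max(2, 0.16 * pitch_x)       # lobe radius
    L  <- 0.45 * pitch_x               # lobe-centre separation
    br <- max(1, 0.45 * rr)            # bridge half-height
    boxes <- stoma_boxes()
    for (k in sto_idx) {
      sel_region <- region == k
      mask[sel_region] <- 0L           # guard + subsidiary: wall class
      if (spec$subsidiary_cells) img[sel_region] <- 112
      lob1 <- (XX - (cx[k] - L / 2))^2 + (YY - cy[k])^2 <= rr^2
      lob2 <- (XX - (cx[k] + L / 2))^2 + (YY - cy[k])^2 <= rr^2
      bridge <- abs(XX - cx[k]) <= L / 2 & abs(YY - cy[k]) <= br
      img[(lob1 | lob2 | bridge) & sel_region] <- 40
      boxes <- rbind(
        boxes,
        stoma_boxes(xmin = ceiling(cx[k] - L / 2 - rr),
                    ymin = ceiling(cy[k] - rr),
                    xmax = floor(cx[k] + L / 2 + rr) + 1,
                    ymax = floor(cy[k] + rr) + 1))
    }

    # trichomes: bright hairs confined to one cell interior; marked white in
    # the truth mask (a no-op there, by construction)
    n_tri <- rpois(1, spec$trichome_rate)
    cell_idx <- setdiff(seq_len(n_act), sto_idx)
    if (n_tri > 0 && length(cell_idx) > 0) {
      for (t in seq_len(min(n_tri, length(cell_idx)))) {
        k <- sample(cell_idx, 1)
        ang <- runif(1, 0, pi)
        hl <- 0.4 * pitch_x
        dxn <- cos(ang); dyn <- sin(ang)
        tproj <- clamp((XX - cx[k]) * dxn + (YY - cy[k]) * dyn, -hl, hl)
        dist2 <- ((XX - cx[k]) - tproj * dxn)^2 + ((YY - cy[k]) - tproj * dyn)^2
        sel <- dist2 <= 1.2^2 & region == k & !wall
        img[sel] <- 235
        mask[sel] <- 1L
      }
    }

    # illumination gradient + Gaussian noise, grayscale replicated to RGB
    ga <- runif(1, -12, 12); gb <- runif(1, -12, 12)
    img <- img + ga * (XX / W - 0.5) + gb * (YY / H - 0.5)
    if (spec$noise_sigma > 0) img <- img + rnorm(H * W, 0, spec$noise_sigma)
    img <- clamp(round(img), 0, 255)

    # wall rasterization can leave sub-cell white slivers (e.g. a lone
    # pixel at a four-corner junction); no annotator would call these
    # cells, so they are reassigned to the wall class before the truth is
    # derived — every remaining white domain is a genuine cell
    repeat {
      lab <- .cpp_label_mat(mask, 4L)
      k <- max(lab)
      if (k == 0) break
      areas <- tabulate(lab[lab > 0], nbins = k)
      small <- which(areas < mean(areas) / 10)
      if (length(small) == 0) break
      mask[matrix(lab %in% small, H, W)] <- 0L
    }

    keep <- box_visible(boxes, W, H)
    kept <- clip_boxes(boxes[keep, , drop = FALSE], W, H)
    n_cells <- max(.cpp_label_mat(mask, 4L), 0L)
    n_stoma <- nrow(kept)
    si <- if (n_stoma + n_cells > 0) 100 * n_stoma / (n_stoma + n_cells) else NA_real_

    truth <- structure(
      list(stoma_boxes = kept, wall_mask = mask, n_stomata = n_stoma,
           n_epidermal_cells = n_cells, stomatal_index_pct = si),
      class = "stomx_scene_truth")
    mic <- micrograph(array(rep(img, 3), dim = c(H, W, 3)),
                      magnification = "x10",
                      image_id = sprintf("scene_seed%d", spec$seed))
    list(micrograph = mic, truth = truth)
  })
}

#' @export
print.stomx_scene_truth <- function(x, ...) {
  cat(sprintf("<stomx_scene_truth> %d stomata, %d epidermal cells, SI %.2f%%\n",
              x$n_stomata, x$n_epidermal_cells, x$stomatal_index_pct))
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes, for each scene, the image PNG, the ground-truth wall-mask PNG
#' (0 = wall, 255 = intracellular), a Pascal VOC XML box file, and one CSV
#' manifest for the whole set. Per-image seeds are derived deterministically
#' from the template seed, so re-running with the same arguments reproduces
#' identical files.
#'
#' @param n_images Number of scenes (>= 1).
#' @param spec_template A [scene_spec()]; its seed anchors the per-image seeds.
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble (`image_id`, `image`, `mask`, `xml`,
#'   `n_stomata`, `n_cells`, `stomatal_index_pct`), invisibly also written to
#'   `manifest.csv`.
#' @export
generate_dataset <- function(n_images, spec_template, out_dir) {
  stopifnot(n_images >= 1, inherits(spec_template, "stomx_scene_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create output dir: ", out_dir))
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    spec_i <- spec_template
    spec_i$seed <- as.integer((spec_template$seed + 7919 * i) %% 2147483647)
    sc <- generate_scene(spec_i)
    id <- sprintf("img_%04d", i)
    img_path <- file.path(out_dir, paste0(id, ".png"))
    mask_path <- file.path(out_dir, paste0(id, "_mask.png"))
    xml_path <- file.path(out_dir, paste0(id, ".xml"))
    sc$micrograph$image_id <- id
    write_micrograph(sc$micrograph, img_path)
    write_mask(sc$truth$wall_mask, mask_path)
    write_voc(sc$truth$stoma_boxes,
              list(filename = basename(img_path),
                   width = spec_i$width_px, height = spec_i$height_px),
              xml_path)
    rows[[i]] <- tibble(
      image_id = id, image = basename(img_path), mask = basename(mask_path),
      xml = basename(xml_path), n_stomata = sc$truth$n_stomata,
      n_cells = sc$truth$n_epidermal_cells,
      stomatal_index_pct = sc$truth$stomatal_index_pct)
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
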