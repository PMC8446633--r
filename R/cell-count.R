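#' Post-processing configuration for cell counting
#'
#' Parameters of the chain that turns a predicted wall/intracellular
#' probability map into an epidermal-cell count: bilateral denoising,
#' binarization, morphological opening of the intracellular class (which
#' closes thin breaks in predicted cell walls), connected-domain labeling,
#' and removal
#' of domains smaller than a fraction (default 1/10) of the mean domain
#' area.
#'
#' @param bilateral_radius Window radius in pixels.
#' @param bilateral_sigma_range Range (intensity) sigma on the `[0, 1]`
#'   probability scale.
#' @param bilateral_sigma_space Spatial sigma in pixels.
#' @param binarize_threshold Threshold on the probability map.
#' @param opening_kernel Odd side of the square structuring element.
#' @param opening_iterations Opening repetitions.
#' @param area_filter_fraction Domains with area strictly below
#'   `fraction * mean(area)` are removed.
#' @param connectivity Pixel adjacency for intracellular domains: 4 or 8.
#' @param apply_bilateral,apply_opening Stage switches (useful when feeding
#'   clean ground-truth masks through the chain).
#' @return Object of class `stomx_post_config`.
#' @export
postprocess_config <- function(bilateral_radius = 4, bilateral_sigma_range = 0.3,
                               bilateral_sigma_space = 4,
                               binarize_threshold = 0.5, opening_kernel = 3,
                               opening_iterations = 1,
                               area_filter_fraction = 1 / 10,
                               connectivity = 4, apply_bilateral = TRUE,
                               apply_opening = TRUE) {
  stopifnot(bilateral_radius >= 1, binarize_threshold >= 0,
            binarize_threshold <= 1, opening_kernel >= 1,
            opening_kernel %% 2 == 1, opening_iterations >= 1,
            area_filter_fraction > 0, area_filter_fraction < 1,
            connectivity %in% c(4, 8))
  structure(
    list(bilateral_radius = as.integer(bilateral_radius),
         bilateral_sigma_range = bilateral_sigma_range,
         bilateral_sigma_space = bilateral_sigma_space,
         binarize_threshold = binarize_threshold,
         opening_kernel = as.integer(opening_kernel),
         opening_iterations = as.integer(opening_iterations),
         area_filter_fraction = area_filter_fraction,
         connectivity = as.integer(connectivity),
         apply_bilateral = isTRUE(apply_bilateral),
         apply_opening = isTRUE(apply_opening)),
    class = "stomx_post_config"
  )
}

#' Bilateral denoising of a probability map
#'
#' Edge-preserving smoothing: each output pixel is the normalized sum of
#' its neighbors weighted by a spatial Gaussian times a range Gaussian, so
#' noise is averaged out while wall/cell edges stay put.
#'
#' @param prob_mask Matrix with values in `[0, 1]`.
#' @param cfg A [postprocess_config()] (radius and sigmas).
#' @return Smoothed matrix in `[0, 1]`.
#' @export
bilateral_denoise <- function(prob_mask, cfg = postprocess_config()) {
  stopifnot(min(prob_mask) >= 0, max(prob_mask) <= 1)
  .cpp_bilateral_mat(prob_mask, cfg$bilateral_radius,
                     cfg$bilateral_sigma_range, cfg$bilateral_sigma_space)
}

#' Binarize a probability map
#'
#' Values `>= threshold` become intracellular (1), the rest wall (0).
#'
#' @param x Numeric matrix in `[0, 1]`.
#' @param threshold Threshold.
#' @return 0/1 integer matrix.
#' @export
binarize <- function(x, threshold = 0.5) {
  matrix(as.integer(x >= threshold), nrow(x), ncol(x))
}

#' Morphological opening of the intracellular class
#'
#' Erosion then dilation with a square structuring element, applied to the
#' intracellular (white) class of the predicted cell network. A break in a
#' predicted wall is a thin white channel; opening removes every white
#' structure too thin to contain the structuring element, so such channels
#' close permanently while the cells (large white regions) are merely
#' smoothed. Isolated white specks inside walls are removed for the same
#' reason. Idempotent for a fixed element.
#'
#' @param mask 0/1 integer matrix.
#' @param cfg A [postprocess_config()] (kernel size and iterations).
#' @return 0/1 integer matrix.
#' @export
morph_open <- function(mask, cfg = postprocess_config()) {
  stopifnot(all(mask %in% c(0L, 1L)))
  kern <- EBImage::makeBrush(cfg$opening_kernel, shape = "box")
  fg <- mask
  for (i in seq_len(cfg$opening_iterations)) {
    fg <- EBImage::dilate(EBImage::erode(fg, kern), kern)
  }
  matrix(as.integer(fg), nrow(mask), ncol(mask))
}

#' Label connected intracellular domains
#'
#' Each maximal connected set of intracellular (1) pixels under the chosen
#' adjacency is one domain — the pipeline's stand-in for one epidermal
#' cell. Labels are contiguous `1..K`.
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 or 8.
#' @return Object of class `stomx_labeling`: `label_grid` (integer matrix,
#'   0 = wall) and `domain_areas` (named integer vector of pixel counts).
#' @export
label_domains <- function(mask, connectivity = 4) {
  stopifnot(all(mask %in% c(0L, 1L)), connectivity %in% c(4, 8))
  grid <- .cpp_label_mat(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                         as.integer(connectivity))
  k <- max(grid)
  areas <- if (k > 0) tabulate(grid[grid > 0], nbins = k) else integer(0)
  names(areas) <- if (k > 0) as.character(seq_len(k)) else character(0)
  structure(list(label_grid = grid, domain_areas = areas,
                 connectivity = as.integer(connectivity)),
            class = "stomx_labeling")
}

#' @export
print.stomx_labeling <- function(x, ...) {
  cat(sprintf("<stomx_labeling> %d domains (%d-connectivity)\n",
              length(x$domain_areas), x$connectivity))
  invisible(x)
}

#' Remove small connected domains
#'
#' The mean pixel area is computed once over all domains; domains with
#' area strictly below `fraction * mean` are removed (incomplete cells at
#' the image edge and residual specks). Survivors are relabeled
#' contiguously.
#'
#' @param labeling A [label_domains()] result.
#' @param fraction Area fraction of the mean (default 1/10).
#' @return List with `labeling` (filtered, relabeled) and `n_cells`.
#' @export
area_filter <- function(labeling, fraction = 1 / 10) {
  stopifnot(inherits(labeling, "stomx_labeling"))
  areas <- labeling$domain_areas
  if (length(areas) == 0) {
    return(list(labeling = labeling, n_cells = 0L))
  }
  thr <- fraction * mean(areas)
  keep <- which(!(areas < thr))
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  grid <- labeling$label_grid
  grid[grid > 0] <- remap[grid[grid > 0]]
  out <- structure(list(label_grid = grid,
                        domain_areas = stats::setNames(areas[keep],
                                                       as.character(seq_along(keep))),
                        connectivity = labeling$connectivity),
                   class = "stomx_labeling")
  list(labeling = out, n_cells = length(keep))
}

#' Count epidermal cells in a probability mask
#'
#' The full post-processing chain: bilateral denoising, binarization,
#' morphological opening of the wall class, connected-domain labeling and
#' small-area filtering; the count of surviving domains is the epidermal
#' cell number. Deterministic.
#'
#' @param prob_mask Probability matrix in `[0, 1]` (a 0/1 mask also works).
#' @param cfg A [postprocess_config()].
#' @return Integer cell count.
#' @export
count_cells <- function(prob_mask, cfg = postprocess_config()) {
  x <- prob_mask
  if (cfg$apply_bilateral) x <- bilateral_denoise(x, cfg)
  m <- binarize(x, cfg$binarize_threshold)
  if (cfg$apply_opening) m <- morph_open(m, cfg)
  lab <- label_domains(m, cfg$connectivity)
  area_filter(lab, cfg$area_filter_fraction)$n_cells
}
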