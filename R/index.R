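#' Stomatal index
#'
#' `100 * s / (s + c)` percent, the ratio of the stomata count to stomata
#' plus epidermal cells. Unlike stomatal density it is largely insensitive
#' to cell expansion, which makes it a diagnostic trait of a genotype or
#' species (at a fixed magnification). When both counts are zero the index
#' is undefined and returned as `NA` (flagged), never as 0.
#'
#' @param n_stomata,n_cells Non-negative counts (vectorized).
#' @return Index in percent, `NA` where undefined.
#' @export
compute_stomatal_index <- function(n_stomata, n_cells) {
  stopifnot(all(n_stomata >= 0), all(n_cells >= 0))
  total <- n_stomata + n_cells
  out <- ifelse(total > 0, 100 * n_stomata / total, NA_real_)
  if (anyNA(out)) warn("stomatal index undefined where no objects were counted")
  out
}

#' Stomatal density
#'
#' Stomata per unit leaf area (pores per mm^2) for a known microscope field
#' of view.
#'
#' @param n_stomata Non-negative count (vectorized).
#' @param field_of_view_mm2 Field of view in mm^2 (> 0); 1.428 mm^2 for the
#'   reference x10 optics, a quarter of that at x20.
#' @return Density in pores/mm^2.
#' @export
compute_density <- function(n_stomata, field_of_view_mm2 = 1.428) {
  stopifnot(all(field_of_view_mm2 > 0), all(n_stomata >= 0))
  n_stomata / field_of_view_mm2
}

# resolve a detector argument: a trained model or a function(micrograph) ->
# scored box tibble (e.g. a truth oracle in tests)
as_detector_fun <- function(detector) {
  if (is.function(detector)) return(detector)
  stopifnot(inherits(detector, "stomx_detector"))
  function(mic) detect_stomata(detector, mic)
}

as_segmenter_fun <- function(segmenter) {
  if (is.function(segmenter)) return(segmenter)
  stopifnot(inherits(segmenter, "stomx_seg_model"))
  function(mic) predict_mask(segmenter, mic)
}

#' Run the stomatal-index pipeline over images
#'
#' For each image: detect and count stomata (score > 0.9), segment and
#' count epidermal cells through the post-processing chain, then compute
#' the stomatal index (and density when a field of view is given).
#' Unreadable images become failed rows; the run continues. Per-stage wall
#' times are accumulated for average-running-time reporting.
#'
#' @param images List of micrographs, pixel arrays, or PNG paths.
#' @param detector Trained `stomx_detector`, or a function mapping a
#'   micrograph to a scored box tibble.
#' @param segmenter Trained `stomx_seg_model`, or a function mapping a
#'   micrograph to a probability mask.
#' @param post_cfg A [postprocess_config()].
#' @param fov_mm2 Optional field of view (mm^2) for density.
#' @param score_threshold Stoma counting threshold.
#' @return A tibble (class `stomx_counts`) with one row per image:
#'   `image_id`, `n_stomata`, `n_cells`, `stomatal_index_pct`,
#'   `density_per_mm2`, `magnification`, `status`; stage timings are
#'   attached as the `"timing"` attribute (see [measure_art()]).
#' @export
run_pipeline <- function(images, detector, segmenter,
                         post_cfg = postprocess_config(), fov_mm2 = NULL,
                         score_threshold = 0.9) {
  det_fun <- as_detector_fun(detector)
  seg_fun <- as_segmenter_fun(segmenter)
  t_stoma <- t_cell <- t_si <- 0
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    rows[[i]] <- tryCatch({
      img <- images[[i]]
      if (is.character(img)) img <- read_micrograph(img)
      if (!inherits(img, "stomx_micrograph")) img <- micrograph(as_pixel_array(img))
      t0 <- proc.time()[["elapsed"]]
      n_sto <- count_stomata(det_fun(img), threshold = score_threshold)
      t1 <- proc.time()[["elapsed"]]
      n_cell <- count_cells(seg_fun(img), post_cfg)
      t2 <- proc.time()[["elapsed"]]
      si <- suppressWarnings(compute_stomatal_index(n_sto, n_cell))
      t3 <- proc.time()[["elapsed"]]
      t_stoma <- t_stoma + (t1 - t0)
      t_cell <- t_cell + (t2 - t1)
      t_si <- t_si + (t3 - t2)
      tibble(image_id = img$image_id, n_stomata = n_sto, n_cells = n_cell,
             stomatal_index_pct = si,
             density_per_mm2 = if (is.null(fov_mm2)) NA_real_
                               else compute_density(n_sto, fov_mm2),
             magnification = img$magnification, status = "ok")
    }, error = function(e) {
      tibble(image_id = if (is.character(images[[i]])) basename(images[[i]])
                        else sprintf("img_%04d", i),
             n_stomata = NA_integer_, n_cells = NA_integer_,
             stomatal_index_pct = NA_real_, density_per_mm2 = NA_real_,
             magnification = "unknown", status = conditionMessage(e))
    })
  }
  out <- dplyr::bind_rows(rows)
  n_ok <- if (nrow(out)) sum(out$status == "ok") else 0L
  attr(out, "timing") <- list(T_stoma = t_stoma, T_cell = t_cell, T_SI = t_si,
                              N = n_ok)
  class(out) <- c("stomx_counts", class(out))
  out
}
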