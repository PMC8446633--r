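test_that("the stomatal index follows its defining ratio", {
  expect_equal(compute_stomatal_index(0, 50), 0)
  expect_equal(compute_stomatal_index(10, 0), 100)
  expect_equal(compute_stomatal_index(27, 135), 100 * 27 / 162, tolerance = 1e-9)
  expect_equal(round(compute_stomatal_index(27, 135), 4), 16.6667)
  expect_warning(und <- compute_stomatal_index(0, 0))
  expect_true(is.na(und))   # flagged, never reported as 0
})

test_that("stomatal density is count over field of view", {
  expect_equal(compute_density(0, 1.428), 0)
  expect_equal(compute_density(31, 1.428), 31 / 1.428, tolerance = 1e-12)
  expect_equal(compute_density(10, 2), compute_density(10, 1) / 2)
  expect_error(compute_density(3, 0))
})

# truth-oracle models: functions that return the exact annotations
oracle_models <- function(scenes) {
  by_id <- stats::setNames(scenes, vapply(scenes, function(s) s$micrograph$image_id, ""))
  list(
    det = function(mic) {
      b <- by_id[[mic$image_id]]$truth$stoma_boxes
      b$score <- rep(1, nrow(b)); b
    },
    seg = function(mic) {
      matrix(as.numeric(by_id[[mic$image_id]]$truth$wall_mask), 256, 256)
    })
}

test_that("the composed pipeline on truth oracles reproduces exact indices", {
  scenes <- study_scenes(301:303)
  om <- oracle_models(scenes)
  res <- run_pipeline(lapply(scenes, function(s) s$micrograph), om$det, om$seg,
                      postprocess_config(apply_opening = FALSE), fov_mm2 = 1.428)
  expect_equal(res$n_stomata, vapply(scenes, function(s) s$truth$n_stomata, 0L))
  expect_equal(res$n_cells,
               vapply(scenes, function(s) s$truth$n_epidermal_cells, 0L))
  expect_equal(res$stomatal_index_pct,
               vapply(scenes, function(s) s$truth$stomatal_index_pct, 0))
  expect_equal(res$density_per_mm2, res$n_stomata / 1.428)
  expect_true(all(res$status == "ok"))
  art <- measure_art(res)
  expect_equal(art$N, 3)
  expect_gte(art$ART, 0)
})

test_that("an injected 12-stomata 68-cell scene yields an index of 15", {
  det <- function(mic) stoma_boxes(xmin = seq(0, 110, 10), ymin = 0,
                                   xmax = seq(5, 115, 10), ymax = 5,
                                   score = rep(0.99, 12))
  seg <- function(mic) {
    m <- matrix(0, 256, 256)
    for (r in 0:3) for (c in 0:16) {
      m[(r * 60 + 2):(r * 60 + 50), (c * 15 + 2):(c * 15 + 13)] <- 1
    }
    m
  }
  mic <- generate_scene(scene_spec(seed = 1))$micrograph
  res <- run_pipeline(list(mic), det, seg, postprocess_config(apply_opening = FALSE))
  expect_equal(res$n_stomata, 12L)
  expect_equal(res$n_cells, 68L)
  expect_equal(res$stomatal_index_pct, 15)
})

test_that("pipeline results are order-independent and failures become rows", {
  scenes <- study_scenes(301:303)
  om <- oracle_models(scenes)
  mics <- lapply(scenes, function(s) s$micrograph)
  r1 <- run_pipeline(mics, om$det, om$seg, postprocess_config(apply_opening = FALSE))
  r2 <- run_pipeline(rev(mics), om$det, om$seg, postprocess_config(apply_opening = FALSE))
  strip <- function(x) {
    attr(x, "timing") <- NULL
    class(x) <- class(tibble::tibble())
    dplyr::arrange(x, image_id)
  }
  expect_equal(strip(r1), strip(r2))
  expect_equal(nrow(run_pipeline(list(), om$det, om$seg)), 0)
  r3 <- run_pipeline(c("/nonexistent/img.png", mics[1]), om$det, om$seg,
                     postprocess_config(apply_opening = FALSE))
  expect_equal(r3$status[2], "ok")
  expect_false(r3$status[1] == "ok")
  expect_true(is.na(r3$n_stomata[1]))
})

test_that("the index is invariant under magnification simulation of truth", {
  # one large scene; cropping to the x20 window keeps the index defined by
  # the surviving truth annotations
  big <- memo("big_scene",
              generate_scene(scene_spec(width_px = 704, height_px = 512,
                                        target_cell_count = 120, seed = 55)))
  r <- simulate_20x(big$micrograph, big$truth$stoma_boxes, big$truth$wall_mask)
  n_sto <- nrow(r$boxes)
  n_cell <- count_cells(r$mask, postprocess_config(apply_opening = FALSE,
                                                   area_filter_fraction = 1e-6))
  # the same counts computed directly on the cropped (unscaled) truth
  crop_mask <- big$truth$wall_mask[1:512, 1:680]
  n_cell_crop <- count_cells(crop_mask, postprocess_config(apply_opening = FALSE,
                                                           area_filter_fraction = 1e-6))
  expect_equal(n_cell, n_cell_crop)
  expect_equal(compute_stomatal_index(n_sto, n_cell),
               compute_stomatal_index(n_sto, n_cell_crop))
})
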