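test_that("bilateral filtering matches a brute-force kernel and preserves constants", {
  flat <- matrix(0.4, 5, 5)
  expect_equal(bilateral_denoise(flat), flat, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    toy <- matrix(runif(9), 3, 3)
    cfg <- postprocess_config(bilateral_radius = 1, bilateral_sigma_range = 0.25,
                              bilateral_sigma_space = 1.5)
    expect_equal(bilateral_denoise(toy, cfg),
                 bilateral_bruteforce(toy, 1, 0.25, 1.5), tolerance = 1e-12)
  }
  # a larger window against the oracle
  big <- matrix(runif(100), 10, 10)
  expect_equal(bilateral_denoise(big, postprocess_config()),
               bilateral_bruteforce(big, 4, 0.3, 4), tolerance = 1e-12)
})

test_that("bilateral filtering preserves step-edge locations", {
  step <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  sm <- bilateral_denoise(step)
  grad_before <- apply(step, 1, function(r) which.max(abs(diff(r))))
  grad_after <- apply(sm, 1, function(r) which.max(abs(diff(r))))
  expect_equal(grad_after, grad_before)
})

test_that("binarization applies the >= threshold rule", {
  expect_true(all(binarize(matrix(0.9, 3, 3), 0.5) == 1L))
  expect_identical(binarize(matrix(c(0.4, 0.6), 1, 2), 0.5),
                   matrix(c(0L, 1L), 1, 2))
  expect_true(all(binarize(matrix(runif(9), 3, 3), 0) == 1L))
})

test_that("opening removes thin white structures and is idempotent", {
  # isolated white pixel inside wall, kernel 3 -> removed
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_true(all(morph_open(m) == 0L))
  # a mask already open w.r.t. the element is unchanged
  open_mask <- matrix(0L, 12, 12); open_mask[3:8, 3:8] <- 1L
  expect_identical(morph_open(open_mask), open_mask)
  # opening twice equals opening once
  set.seed(14)
  r <- matrix(rbinom(400, 1, 0.6), 20, 20)
  once <- morph_open(r)
  expect_identical(morph_open(once), once)
  # a one-pixel break in a wall closes (the white channel is removed)
  walled <- matrix(1L, 9, 9); walled[, 5] <- 0L; walled[5, 5] <- 1L
  closed <- morph_open(walled)
  expect_equal(length(label_domains(closed, 4)$domain_areas), 2)
  expect_equal(length(label_domains(walled, 4)$domain_areas), 1)
})

test_that("domain labeling distinguishes 4- and 8-connectivity", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- m[2, 2] <- 1L  # touch diagonally only
  expect_equal(length(label_domains(m, 4)$domain_areas), 2)
  expect_equal(length(label_domains(m, 8)$domain_areas), 1)
  expect_equal(length(label_domains(matrix(0L, 4, 4), 4)$domain_areas), 0)
  lab <- label_domains(m, 4)
  expect_equal(sum(lab$domain_areas), sum(m))
  expect_equal(sort(unique(as.vector(lab$label_grid))), c(0L, 1L, 2L))
})

test_that("domain labeling equals the flood-fill oracle on random masks", {
  set.seed(77)
  for (i in 1:30) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.3, 0.7)), 32, 32)
    for (conn in c(4, 8)) {
      expect_equal(length(label_domains(m, conn)$domain_areas),
                   flood_fill_count(m, conn))
    }
  }
})

test_that("domain labeling agrees with EBImage's component labeling", {
  set.seed(5)
  m <- matrix(rbinom(1024, 1, 0.5), 32, 32)
  eb <- max(EBImage::bwlabel(m))
  # EBImage's bwlabel fills 4-connected components
  expect_equal(length(label_domains(m, 4)$domain_areas), eb)
})

test_that("the area filter removes sub-threshold domains in a single pass", {
  grid <- matrix(0L, 20, 40)
  grid[2:11, 2:11] <- 1L     # 100 px
  grid[2:11, 14:23] <- 1L    # 100 px
  grid[2:11, 26:35] <- 1L    # 100 px
  lab <- label_domains(grid, 4)
  expect_equal(area_filter(lab)$n_cells, 3)  # equal areas: none removed
  grid[15, 2:6] <- 1L        # 5 px speck: mean 76.25, threshold 7.625
  lab <- label_domains(grid, 4)
  out <- area_filter(lab)
  expect_equal(out$n_cells, 3)
  expect_equal(length(out$labeling$domain_areas), 3)
  expect_equal(sort(unique(as.vector(out$labeling$label_grid))), 0:3)
  # fraction -> 0 recovers the unfiltered count; the filter never adds
  expect_equal(area_filter(lab, fraction = 1e-9)$n_cells, 4)
  expect_lte(area_filter(lab)$n_cells, length(lab$domain_areas))
  empty <- label_domains(matrix(0L, 5, 5), 4)
  expect_equal(area_filter(empty)$n_cells, 0)
})

test_that("a 45-domain labeling with six small domains filters to 39 cells", {
  # constructed to the published post-processing example: 39 of 45
  # connected domains survive the 1/10-of-mean-area rule
  H <- 120; W <- 130
  grid <- matrix(0L, H, W)
  place <- function(y, x, h, w) grid[y:(y + h - 1), x:(x + w - 1)] <<- 1L
  k <- 0
  for (r in 0:5) for (c in 0:6) {   # 42 regular cells of 15x12 = 180 px
    k <- k + 1
    if (k > 39) break
    place(3 + r * 18, 3 + c * 17, 15, 12)
  }
  # six edge fragments well below a tenth of the mean area
  for (c in 0:5) place(112, 3 + c * 17, 2, 4)
  lab <- label_domains(grid, 4)
  expect_equal(length(lab$domain_areas), 45)
  expect_equal(area_filter(lab)$n_cells, 39)
})

test_that("count_cells is exact on ground-truth masks and deterministic", {
  for (seed in c(3, 18)) {
    tr <- generate_scene(scene_spec(seed = seed))$truth
    cfg <- postprocess_config(apply_opening = FALSE)
    expect_equal(count_cells(tr$wall_mask, cfg), tr$n_epidermal_cells)
    expect_equal(count_cells(tr$wall_mask), tr$n_epidermal_cells)
    expect_equal(count_cells(tr$wall_mask, cfg), count_cells(tr$wall_mask, cfg))
  }
  expect_equal(count_cells(matrix(0, 16, 16)), 0)
})
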