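test_that("VOC round trip is lossless and uses the documented conventions", {
  boxes <- stoma_boxes(xmin = c(0, 10, 100), ymin = c(0, 20, 50),
                       xmax = c(10, 40, 140), ymax = c(10, 45, 80))
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc(boxes, list(filename = "img.png", width = 256, height = 256), path)
  back <- read_voc(path)
  expect_equal(back, boxes)
  # file stores 1-based inclusive coordinates
  doc <- xml2::read_xml(path)
  first <- xml2::xml_find_first(doc, ".//bndbox")
  expect_equal(xml2::xml_text(xml2::xml_find_first(first, ".//xmin")), "1")
  expect_equal(xml2::xml_text(xml2::xml_find_first(first, ".//xmax")), "10")
})

test_that("a VOC box (1,1,10,10) reads as the half-open (0,0,10,10)", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<annotation><size><width>20</width><height>20</height></size>",
               "<object><name>stoma</name><bndbox><xmin>1</xmin><ymin>1</ymin>",
               "<xmax>10</xmax><ymax>10</ymax></bndbox></object></annotation>"),
             path)
  b <- read_voc(path)
  expect_equal(unlist(b[1, ]), c(xmin = 0, ymin = 0, xmax = 10, ymax = 10))
})

test_that("empty object lists and malformed boxes are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc(stoma_boxes(), list(filename = "x", width = 10, height = 10), path)
  expect_equal(nrow(read_voc(path)), 0)
  writeLines(c("<annotation><object><bndbox><xmin>9</xmin><ymin>1</ymin>",
               "<xmax>3</xmax><ymax>5</ymax></bndbox></object></annotation>"),
             path)
  expect_error(read_voc(path), "bndbox")
  writeLines("<annotation><object><bndbox><ymin>1</ymin></bndbox></object></annotation>",
             path)
  expect_error(read_voc(path), "xmin")
})

test_that("mask I/O round-trips and applies the 127 threshold rule", {
  path <- withr::local_tempfile(fileext = ".png")
  set.seed(4)
  mask <- matrix(rbinom(80 * 70, 1, 0.5), 80, 70)
  write_mask(mask, path)
  expect_identical(read_mask(path), mask)
  # gray values {30, 200} map to {0, 1}
  png::writePNG(matrix(c(30, 200, 30, 200) / 255, 2, 2), path)
  expect_identical(read_mask(path), matrix(c(0L, 1L, 0L, 1L), 2, 2))
  png::writePNG(matrix(1, 4, 4), path)
  expect_true(all(read_mask(path) == 1L))
})

test_that("fold splits are deterministic, exclusive and balanced", {
  ids <- sprintf("img%04d", 1:1000)
  f1 <- make_folds(ids, k = 5, seed = 3)
  f2 <- make_folds(ids, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1$fold)), 1:5)
  expect_true(all(table(f1$fold) == 200))
  expect_setequal(f1$image_id, ids)
  f3 <- make_folds(sprintf("i%d", 1:10), k = 5, seed = 1)
  expect_true(all(table(f3$fold) == 2))
})

test_that("90-degree rotation permutes a centered box exactly and preserves cell counts", {
  sc <- generate_scene(scene_spec(seed = 6))
  box <- stoma_boxes(100, 60, 150, 90)
  r <- rotate_annotated(sc$micrograph, box, sc$truth$wall_mask, 90)
  # clockwise: (x, y) -> (H - y, x) on corner coordinates, H = 256
  expect_equal(unlist(r$boxes[1, ]),
               c(xmin = 256 - 90, ymin = 100, xmax = 256 - 60, ymax = 150))
  expect_equal(flood_fill_count(r$mask, 4), sc$truth$n_epidermal_cells)
  r4 <- rotate_annotated(r$micrograph, r$boxes, r$mask, 270)
  expect_identical(r4$mask, sc$truth$wall_mask)
})

test_that("45-degree rotation expands the canvas and circumscribes boxes", {
  px <- matrix(128, 100, 100)
  mic <- micrograph(array(rep(px, 3), dim = c(100, 100, 3)))
  box <- stoma_boxes(40, 40, 60, 60)
  r <- rotate_annotated(mic, box, NULL, 45)
  expect_equal(dim(r$micrograph$pixels)[1:2], c(142, 142))
  b <- r$boxes[1, ]
  # the rotated 20x20 square circumscribes to ~28.3 px, centred on the canvas
  expect_equal(b$xmax - b$xmin, 20 * sqrt(2), tolerance = 1e-6)
  expect_equal((b$xmin + b$xmax) / 2, (142 - 1) / 2, tolerance = 0.51)
})

test_that("offline augmentation emits originals plus three rotations", {
  sc1 <- generate_scene(scene_spec(seed = 1))
  recs <- list(list(micrograph = sc1$micrograph, boxes = sc1$truth$stoma_boxes))
  out <- offline_augment(recs)
  expect_length(out, 4)
  expect_length(offline_augment(list()), 0)
  expect_identical(out[[1]]$micrograph$pixels, sc1$micrograph$pixels)
})

test_that("online augmentation transforms image and mask identically", {
  sc <- generate_scene(scene_spec(seed = 8))
  # forcing both probabilities to miss gives the identity
  nochange <- online_augment(sc$micrograph, sc$truth$wall_mask,
                             p_affine = 0, p_rot90 = 0)
  expect_identical(nochange$image, sc$micrograph$pixels)
  expect_identical(nochange$mask, sc$truth$wall_mask)
  # forcing the 90-degree branch rotates the mask exactly as the image
  set.seed(1)
  rot <- online_augment(sc$micrograph, sc$truth$wall_mask,
                        p_affine = 0, p_rot90 = 1)
  ref <- rotate_annotated(sc$micrograph, NULL, sc$truth$wall_mask, 90)
  expect_identical(rot$mask, ref$mask)
  expect_identical(rot$image, ref$micrograph$pixels)
})

test_that("online augmentation frequencies match the configured probabilities", {
  px <- array(128, dim = c(64, 64, 3))
  mask <- matrix(1L, 64, 64); mask[10, ] <- 0L  # marker row
  set.seed(99)
  n <- 3000
  n_rot <- 0; n_aff <- 0
  for (i in seq_len(n)) {
    out <- online_augment(px, mask)
    ap <- attr(out, "applied")
    n_aff <- n_aff + ap[["affine"]]
    n_rot <- n_rot + ap[["rot90"]]
  }
  # binomial 3-sigma bands around 0.2 and 0.5
  expect_lt(abs(n_aff / n - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(n_rot / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("x20 simulation crops, cubically enlarges and filters boxes", {
  set.seed(12)
  big <- micrograph(array(round(runif(1360 * 1024 * 3, 0, 255)),
                          dim = c(1024, 1360, 3)))
  boxes <- stoma_boxes(xmin = c(10, 700, 670), ymin = c(10, 30, 100),
                       xmax = c(50, 740, 700), ymax = c(30, 50, 115))
  r <- simulate_20x(big, boxes)
  expect_equal(dim(r$micrograph$pixels)[1:2], c(1024, 1360))
  expect_equal(r$micrograph$magnification, "x20")
  # box fully inside the window doubles exactly
  expect_equal(unlist(r$boxes[1, ]), c(xmin = 20, ymin = 20, xmax = 100, ymax = 60))
  # the box beyond the 680x512 window is dropped, and the straddler with
  # only a third of its length inside fails the half-at-edge rule
  expect_equal(nrow(r$boxes), 1)
  expect_error(simulate_20x(micrograph(array(0, dim = c(100, 100, 3)))),
               "smaller")
})

test_that("the enlargement uses cubic, not linear, interpolation", {
  # a ramp with a kink: cubic interpolation overshoots, bilinear cannot
  m <- matrix(rep(c(rep(0, 8), rep(255, 8)), each = 16), 16, 16, byrow = TRUE)
  cub <- resize_image(m, 32, 32, "cubic")
  lin <- resize_image(m, 32, 32, "bilinear")
  expect_true(min(cub) < -1)   # undershoot is the cubic signature
  expect_true(min(lin) >= 0)
  expect_true(all(abs(dim(cub) - c(32, 32)) == 0))
})
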