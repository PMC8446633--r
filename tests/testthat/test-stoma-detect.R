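test_that("smooth L1 evaluates both branches and is continuous at |x| = 1", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(0.5), 0.125)
  expect_equal(smooth_l1(2), 1.5)
  expect_equal(smooth_l1(1 - 1e-12), smooth_l1(1 + 1e-12), tolerance = 1e-9)
  expect_equal(smooth_l1(1), 0.5)
  expect_equal(smooth_l1(-2), 1.5)
  expect_true(all(smooth_l1(seq(-3, 3, 0.1)) >= 0))
})

test_that("cosine schedule hits the protocol endpoints and never increases", {
  det <- detector_config()
  expect_equal(cosine_lr(0, det), 5e-4)
  expect_equal(cosine_lr(det$epochs, det), 5e-5)
  expect_equal(det$epochs, 20L)
  expect_equal(cosine_lr(10, det), (5e-4 + 5e-5) / 2)
  seg <- seg_config()
  expect_equal(cosine_lr(0, seg), 1e-4)
  expect_equal(cosine_lr(seg$epochs, seg), 1e-5)
  expect_equal(seg$epochs, 200L)
  lrs <- vapply(0:20, cosine_lr, numeric(1), cfg = det)
  expect_true(all(diff(lrs) <= 0))
})

test_that("the two-term detector loss matches its closed forms", {
  cfg <- detector_config()
  # perfect classification, zero residuals
  expect_equal(detector_loss(matrix(c(0, 1), 1), 1,
                             matrix(0, 1, 4), matrix(0, 1, 4), cfg), 0,
               tolerance = 1e-9)
  # uniform two-class prediction on one positive anchor, zero residual
  expect_equal(detector_loss(matrix(0.5, 1, 2), 1,
                             matrix(0, 1, 4), matrix(0, 1, 4), cfg),
               log(2), tolerance = 1e-9)
  # doubling lambda doubles the regression term
  probs <- matrix(c(0.2, 0.8), 1)
  d <- matrix(0.5, 1, 4); t0 <- matrix(0, 1, 4)
  base <- detector_loss(probs, 1, d, t0, cfg)
  cfg2 <- cfg; cfg2$lambda_reg <- 20
  doubled <- detector_loss(probs, 1, d, t0, cfg2)
  reg_term <- base - (-log(0.8))
  expect_equal(doubled - (-log(0.8)), 2 * reg_term, tolerance = 1e-9)
  expect_equal(reg_term, 10 * 4 * 0.125, tolerance = 1e-9)
  # no positives: regression term contributes nothing
  expect_equal(detector_loss(matrix(c(0.9, 0.1), 1), 0,
                             matrix(3, 1, 4), matrix(0, 1, 4), cfg),
               -log(0.9), tolerance = 1e-9)
})

test_that("stomata counting applies the strict score rule", {
  expect_equal(count_stomata(c(0.95, 0.91, 0.89)), 2)
  expect_equal(count_stomata(stoma_boxes()), 0)
  expect_equal(count_stomata(c(0.9)), 0)  # strictly greater than
  # a proposal set like the published filtration example: 112 scored
  # boxes of which exactly 32 clear the 0.9 threshold
  set.seed(31)
  scores <- c(runif(32, 0.905, 0.999), runif(80, 0.05, 0.9))
  expect_length(scores, 112)
  expect_equal(count_stomata(scores), 32)
  # permutation-invariant and monotone under added boxes
  expect_equal(count_stomata(sample(scores)), 32)
  expect_gte(count_stomata(c(scores, 0.95)), count_stomata(scores))
})

test_that("NMS keeps the higher-scored of overlapping boxes, deterministically", {
  b <- stoma_boxes(xmin = c(10, 10, 50), ymin = c(10, 10, 50),
                   xmax = c(30, 30, 70), ymax = c(30, 30, 70),
                   score = c(0.95, 0.94, 0.80))
  out <- stomx:::nms_boxes(b, 0.5)
  expect_equal(nrow(out), 2)
  expect_equal(out$score[1], 0.95)
  # exact ties break lexicographically by (xmin, ymin)
  tie <- stoma_boxes(xmin = c(20, 10), ymin = c(5, 5),
                     xmax = c(40, 30), ymax = c(25, 25),
                     score = c(0.9, 0.9))
  o1 <- stomx:::nms_boxes(tie, 0.3)
  o2 <- stomx:::nms_boxes(tie[2:1, ], 0.3)
  expect_equal(o1$xmin[1], 10)
  expect_identical(o1, o2)
})

test_that("detector config validates the protocol invariants", {
  expect_error(detector_config(lr_initial = 1e-5, lr_final = 1e-4))
  expect_error(detector_config(epochs = 0))
  expect_error(detector_config(anchor_scales = c(0, 8)))
  cfg <- detector_config()
  expect_equal(cfg$anchor_scales, c(4, 8, 16))
  expect_equal(cfg$anchor_ratios, c(0.5, 1, 2))
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$lambda_reg, 10)
  expect_equal(cfg$input_size, c(800L, 600L))
})

test_that("anchor assignment encodes exact regression targets", {
  cfg <- detector_config(input_size = c(64, 64), widths = c(4, 8), seed = 1)
  anch <- stomx:::anchor_grid(cfg)
  gt <- stoma_boxes(10, 12, 42, 28)
  set.seed(2)
  asg <- stomx:::assign_anchors(anch, gt, cfg)
  pos <- which(asg$labels == 1)
  expect_gt(length(pos), 0)
  i <- pos[1]
  gw <- 32; gh <- 16; gx <- 26; gy <- 20
  expect_equal(asg$reg_t[1, i], unname((gx - anch[i, "cx"]) / anch[i, "w"]))
  expect_equal(asg$reg_t[3, i], unname(log(gw / anch[i, "w"])))
  # decoding the target deltas from the anchor recovers the box exactly
  cx <- anch[i, "cx"] + asg$reg_t[1, i] * anch[i, "w"]
  w <- anch[i, "w"] * exp(asg$reg_t[3, i])
  expect_equal(unname(cx - w / 2), 10)
})
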