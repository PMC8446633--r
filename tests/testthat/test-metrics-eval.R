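test_that("box IoU matches area arithmetic and its invariants", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150, tolerance = 1e-9)
  a <- c(2, 3, 9, 8); b <- c(4, 1, 12, 6)
  expect_equal(iou(a, b), iou(b, a))
})

test_that("Dice coefficient matches pixel counts and its invariants", {
  m1 <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice(m1, m1), 1)
  expect_equal(dice(m1, 1 - m1), 0)
  # half-overlapping equal-area masks on a 4x4 grid
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[1:2, 2:3] <- 1L
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
})

test_that("counting accuracy follows the absolute-error formula", {
  expect_equal(counting_accuracy(100, 100), 1)
  expect_equal(counting_accuracy(98, 100), 0.98)
  expect_equal(counting_accuracy(150, 100), 0.5)
  expect_equal(counting_accuracy(250, 100), -0.5)  # gross overcount goes negative
  expect_warning(out <- counting_accuracy(5, 0))
  expect_true(is.na(out))
})

test_that("counting precision is a log ratio, antisymmetric, undefined at zero", {
  expect_equal(counting_precision(100, 100), 0)
  expect_equal(counting_precision(50, 100), log10(0.5), tolerance = 1e-9)
  expect_equal(counting_precision(100, 50), log10(2), tolerance = 1e-9)
  set.seed(8)
  m <- sample(1:50, 10); a <- sample(1:50, 10)
  expect_equal(counting_precision(m, a), -counting_precision(a, m),
               tolerance = 1e-12)
  expect_warning(p0 <- counting_precision(0, 10))
  expect_true(is.na(p0))
  expect_warning(p1 <- counting_precision(10, 0))
  expect_true(is.na(p1))
  # natural-log switch
  expect_equal(counting_precision(50, 100, base = exp(1)), log(0.5))
})

test_that("index accuracy and precision reuse the counting forms", {
  expect_equal(index_accuracy(20, 20), 1)
  expect_equal(index_precision(20, 20), 0)
  expect_equal(index_accuracy(16, 20), 0.8)
  expect_equal(index_precision(10, 20), log10(0.5), tolerance = 1e-9)
})

test_that("identity regression reports R2 about y = x and RMSE", {
  f <- identity_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(f$r2, 1); expect_equal(f$rmse, 0)
  f2 <- identity_regression(c(1, 2, 3), c(1, 2, 4))
  expect_equal(f2$rmse, sqrt(1 / 3), tolerance = 1e-9)
  expect_equal(f2$r2, 0.5, tolerance = 1e-9)
  x <- c(4, 9, 13, 20)
  f3 <- identity_regression(x, x + 2)   # constant shift: RMSE = |c|
  expect_equal(f3$rmse, 2, tolerance = 1e-9)
  expect_equal(glance(f3)$r.squared, f3$r2)
  expect_equal(nrow(tidy(f3)), 4)
  # R2 = 1 iff RMSE = 0 on non-degenerate data
  expect_true(xor(f2$r2 == 1, f2$rmse > 0))
})

test_that("average precision reproduces hand-computable PR curves", {
  tr <- stoma_boxes(0, 0, 10, 10)
  # one truth; higher-scored detection is a miss, lower-scored a hit
  de <- stoma_boxes(xmin = c(50, 0), ymin = c(50, 0),
                    xmax = c(60, 10), ymax = c(60, 10), score = c(0.9, 0.8))
  r <- average_precision(de, tr)
  expect_equal(r$AP, 0.5, tolerance = 1e-9)
  expect_equal(r$n_tp, 1); expect_equal(r$n_fp, 1); expect_equal(r$n_fn, 0)
  # every truth matched by one high-score detection, no false positives
  tr3 <- stoma_boxes(xmin = c(0, 20, 40), ymin = 0, xmax = c(10, 30, 50), ymax = 10)
  de3 <- tr3; de3$score <- c(0.9, 0.8, 0.7)
  expect_equal(average_precision(de3, tr3)$AP, 1)
  expect_warning(und <- average_precision(de3, stoma_boxes()))
  expect_true(is.na(und$AP))
})

test_that("a true positive requires IoU strictly above the 0.6 threshold", {
  tr <- stoma_boxes(0, 0, 10, 10)
  # IoU exactly 0.6: 10x6 overlap of a 10x10 truth with a 10x... construct
  de <- stoma_boxes(0, 2.5, 10, 12.5, score = 0.9)  # IoU = 75/125 = 0.6
  expect_equal(iou(c(0, 2.5, 10, 12.5), c(0, 0, 10, 10)), 0.6, tolerance = 1e-12)
  r <- average_precision(de, tr)
  expect_equal(r$n_tp, 0)
})

test_that("average precision equals the exhaustive threshold-sweep oracle", {
  for (seed in 1:200) {
    inst <- random_detection_instance(seed)
    got <- average_precision(inst$detections, inst$truths)$AP
    want <- ap_threshold_sweep(inst$detections, inst$truths)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("trait summaries report the table layout statistics", {
  rec <- tibble::tibble(
    trait = rep(c("stomata", "cells"), each = 4),
    manual = c(10, 12, 8, 11, 100, 110, 95, 105),
    automatic = c(10, 11, 8, 12, 98, 112, 95, 101))
  rep_tbl <- summarize_counts(rec)
  expect_equal(nrow(rep_tbl), 2)
  st <- rep_tbl[rep_tbl$trait == "stomata", ]
  acc <- counting_accuracy(c(10, 11, 8, 12), c(10, 12, 8, 11))
  expect_equal(st$accuracy_mean, mean(acc))
  expect_equal(st$accuracy_min, min(acc))
  expect_equal(st$pearson_r, cor(c(10, 12, 8, 11), c(10, 11, 8, 12)))
  expect_equal(st$cv_automatic, sd(c(10, 11, 8, 12)) / mean(c(10, 11, 8, 12)))
})

test_that("paired magnification comparison matches the textbook t-test", {
  a <- c(16.2, 17.9, 15.4)
  b <- c(13.1, 14.6, 13.9)
  out <- compare_magnifications(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(out$statistic, t_hand, tolerance = 1e-9)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, 2 * stats::pt(-abs(t_hand), df = 2), tolerance = 1e-9)
  expect_warning(flag <- compare_magnifications(a, a))
  expect_true(is.na(flag$statistic))
  expect_equal(cv(c(2, 2, 2)), 0)
})

test_that("average running time is the stage-total over image count", {
  tr <- measure_art(list(T_stoma = 2, T_cell = 1, T_SI = 0.5, N = 10))
  expect_equal(tr$ART, 0.35)
  expect_error(measure_art(list(T_stoma = 1, T_cell = 1, T_SI = 1, N = 0)))
  half <- measure_art(list(T_stoma = 2, T_cell = 1, T_SI = 0.5, N = 20))
  expect_equal(half$ART, 0.35 / 2)
})
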