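test_that("metric formulas reproduce the worked example", {
  r <- compute_metrics(confusion_counts(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$dice, 0.75)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$precision, 0.75)
  expect_equal(r$f2, 0.75)
  expect_equal(r$specificity, 5 / 6)
  expect_equal(r$iou_polyp, 0.6)
  expect_equal(r$mean_iou, (0.6 + 5 / 7) / 2)
})

test_that("a perfect prediction scores one everywhere", {
  r <- compute_metrics(confusion_counts(TP = 40, FP = 0, TN = 60, FN = 0))
  metrics <- unlist(r[c("accuracy", "sensitivity", "specificity", "precision",
                        "iou_polyp", "iou_background", "mean_iou", "dice",
                        "f2")])
  expect_true(all(metrics == 1))
})

test_that("confusion counting matches the per-pixel oracle", {
  withr::with_seed(41, {
    for (i in 1:20) {
      pred <- matrix(rbinom(256, 1, 0.4), 16, 16)
      truth <- matrix(rbinom(256, 1, 0.3), 16, 16)
      got <- confusion_from_masks(pred, truth)
      ref <- oracle_metrics(pred, truth)
      expect_equal(got$TP, ref$TP)
      expect_equal(got$FP, ref$FP)
      expect_equal(got$TN, ref$TN)
      expect_equal(got$FN, ref$FN)
    }
  })
  expect_error(confusion_from_masks(matrix(0, 2, 2), matrix(0, 3, 2)),
               "resolution")
  expect_error(confusion_from_masks(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
  # complementary masks share no correct pixel
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  cc <- confusion_from_masks(1 - m, m)
  expect_equal(cc$TP + cc$TN, 0)
})

test_that("every metric stays in [0, 1] and Dice relates to polyp IoU", {
  withr::with_seed(42, {
    for (i in 1:200) {
      cts <- as.list(rpois(4, lambda = sample(c(0.5, 5, 50), 1)))
      names(cts) <- c("TP", "FP", "TN", "FN")
      if (Reduce(`+`, cts) == 0) cts$TN <- 1
      r <- compute_metrics(do.call(confusion_counts, cts))
      vals <- unlist(r[c("accuracy", "sensitivity", "specificity",
                         "precision", "iou_polyp", "iou_background",
                         "mean_iou", "dice", "f2")])
      expect_true(all(vals >= 0 & vals <= 1))
      expect_equal(r$dice, 2 * r$iou_polyp / (1 + r$iou_polyp))
    }
  })
})

test_that("swapping class labels swaps the class-conditional metrics", {
  r <- compute_metrics(confusion_counts(TP = 7, FP = 2, TN = 31, FN = 5))
  sw <- compute_metrics(confusion_counts(TP = 31, FP = 5, TN = 7, FN = 2))
  expect_equal(r$sensitivity, sw$specificity)
  expect_equal(r$specificity, sw$sensitivity)
  expect_equal(r$iou_polyp, sw$iou_background)
  expect_equal(r$iou_background, sw$iou_polyp)
  expect_equal(r$mean_iou, sw$mean_iou)
})

test_that("zero-denominator cases follow the vacuous-truth rule", {
  # nothing to find and nothing found: all metrics one, but flagged
  r <- compute_metrics(confusion_counts(TP = 0, FP = 0, TN = 64, FN = 0))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$iou_polyp, 1)
  expect_true(r$degenerate)
  # nothing to find but false alarms raised
  r2 <- compute_metrics(confusion_counts(TP = 0, FP = 3, TN = 61, FN = 0))
  expect_equal(r2$sensitivity, 0)
  expect_equal(r2$precision, 0)
  expect_equal(r2$iou_polyp, 0)
})

test_that("per-image aggregation averages metrics arithmetically", {
  r1 <- compute_metrics(confusion_counts(TP = 10, FP = 0, TN = 90, FN = 0))
  r2 <- compute_metrics(confusion_counts(TP = 5, FP = 5, TN = 85, FN = 5))
  expect_equal(aggregate_per_image(list(r1))$accuracy, r1$accuracy)
  agg <- aggregate_per_image(list(r1, r2))
  expect_equal(agg$accuracy, mean(c(r1$accuracy, r2$accuracy)))
  expect_equal(agg$accuracy, 0.95)
  expect_identical(agg$aggregation_mode, "per_image_mean")
  # permutation invariance
  expect_equal(aggregate_per_image(list(r2, r1))$dice, agg$dice)
  expect_error(aggregate_per_image(list()), "empty")
})

test_that("dataset-aggregate mean IoU averages the two class IoUs", {
  r <- compute_metrics(confusion_counts(TP = 20, FP = 10, TN = 60, FN = 10),
                       aggregation_mode = "dataset_aggregate")
  expect_equal(r$mean_iou, (r$iou_polyp + r$iou_background) / 2)
})

test_that("accuracy binning reproduces the six reporting ranges", {
  h <- bin_accuracies(c(0.95, 0.85, 0.30))
  expect_identical(h$n, c(1L, 1L, 0L, 0L, 0L, 1L))
  expect_identical(bin_accuracies(numeric(0))$n, integer(6))
  # boundaries land in the upper-inclusive bin
  expect_identical(bin_accuracies(c(0.9, 0.8999, 0.5, 0.4999))$n,
                   c(1L, 1L, 0L, 0L, 1L, 1L))
  withr::with_seed(44, {
    a <- runif(356)
    expect_equal(sum(bin_accuracies(a)$n), 356)
  })
  expect_error(bin_accuracies(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evaluate_masks ties the pieces together on disk", {
  dir <- withr::local_tempdir()
  pd <- file.path(dir, "pred"); td <- file.path(dir, "truth")
  dir.create(pd); dir.create(td)
  withr::with_seed(45, {
    for (i in 1:4) {
      t <- matrix(rbinom(64, 1, 0.3), 8, 8)
      p <- t; if (i > 2) p[1, ] <- 1 - p[1, ]
      write_mask(t, file.path(td, sprintf("s%02d.png", i)))
      write_mask(p, file.path(pd, sprintf("s%02d.png", i)))
    }
  })
  res <- evaluate_masks(pd, td)
  expect_identical(nrow(res$per_image), 4L)
  expect_equal(res$per_image$accuracy[1], 1)
  expect_equal(sum(res$histogram$n), 4)
  expect_s3_class(res$dataset_aggregate, "metric_report")
})
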