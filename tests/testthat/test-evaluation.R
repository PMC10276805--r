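test_that("confusion counts cells with malignant as the positive class", {
  cm <- confusion(c("malignant", "benign"), c("malignant", "benign"))
  expect_equal(unlist(cm[c("tn", "fp", "fn", "tp")]), c(tn = 1L, fp = 0L, fn = 0L, tp = 1L))
  cm2 <- confusion("benign", "malignant")
  expect_equal(cm2$fp, 1L)
  expect_equal(cm2$tn + cm2$fn + cm2$tp, 0L)

  set.seed(9)
  truth <- sample(c("benign", "malignant"), 200, replace = TRUE)
  pred <- sample(c("benign", "malignant"), 200, replace = TRUE)
  cm3 <- confusion(truth, pred)
  expect_equal(cm3$tn + cm3$fp + cm3$fn + cm3$tp, 200L)

  expect_error(confusion(c("benign", "malignant"), "benign"), "equal length")
  expect_error(confusion(c("benign", "odd"), c("benign", "benign")), "labels")
})

test_that("metrics implement the five ratios with NA for empty denominators", {
  ms <- classification_metrics(as_confusion(tn = 50, fp = 10, fn = 5, tp = 35))
  expect_equal(ms$accuracy, 85 / 100)
  expect_equal(ms$sensitivity, 35 / 40)
  expect_equal(ms$specificity, 50 / 60)
  expect_equal(ms$ppv, 35 / 45)
  expect_equal(ms$npv, 50 / 55)
  expect_equal(sum(ms$cell_fractions), 1, tolerance = 1e-12)

  nopos <- classification_metrics(as_confusion(tn = 10, fp = 0, fn = 0, tp = 0))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$ppv))
  expect_equal(nopos$accuracy, 1)

  expect_error(classification_metrics(as_confusion(0, 0, 0, 0)), "empty-input")
  expect_error(as_confusion(-1, 0, 0, 0), "non-negative")
})

test_that("self-comparison is perfect", {
  x <- rep(c("benign", "malignant"), times = c(7, 3))
  ms <- classification_metrics(confusion(x, x))
  expect_equal(ms$accuracy, 1)
  expect_equal(ms$sensitivity, 1)
  expect_equal(ms$specificity, 1)
})

test_that("half-up rounding and display formatting match the reporting rules", {
  expect_equal(round_half_up(0.9745, 3), 0.975)
  expect_equal(round_half_up(0.0005, 3), 0.001)
  expect_equal(round_half_up(0.97449, 3), 0.974)
  expect_identical(format_metric(1), "1.0")
  expect_identical(format_metric(0.98), "0.980")
  expect_identical(format_metric(NA_real_), "NA")
})

test_that("cluster eligibility keeps >= 5 retained patches", {
  cl <- data.frame(id = letters[1:4], n_patches = c(4, 5, 6, 49))
  kept <- filter_eligible(cl)
  expect_equal(kept$id, c("b", "c", "d"))
  all_ok <- data.frame(id = letters[1:3], n_patches = c(5, 7, 9))
  expect_equal(filter_eligible(all_ok), all_ok)
})

test_that("evaluate_run joins, filters and reports per modality", {
  truth <- data.frame(id = sprintf("c%d", 1:6),
                      label = rep(c("benign", "malignant"), each = 3),
                      n_patches = c(9, 9, 4, 9, 9, 9))
  pred <- data.frame(id = rep(truth$id, 2),
                     modality = rep(c("color", "ri"), each = 6),
                     label = rep(truth$label, 2))
  rep_ <- evaluate_run(pred, truth, level = "cluster", min_patches = 5)
  expect_equal(nrow(rep_), 2L)
  expect_true(all(rep_$n == 5))      # the 4-patch cluster is excluded
  expect_true(all(rep_$accuracy == 1))

  patch_rep <- evaluate_run(pred[pred$modality == "color", ],
                            truth[, c("id", "label")], level = "patch")
  expect_equal(patch_rep$n, 6L)

  bad <- pred
  bad$id[1] <- "nope"
  expect_error(evaluate_run(bad, truth, level = "cluster"), "data-integrity")
})
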