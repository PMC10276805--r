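mk_scores <- function(v, id = "c1", dims = c(3, 3)) {
  grid <- expand.grid(grid_row = seq_len(dims[1]), grid_col = seq_len(dims[2]))
  data.frame(cluster_id = id, grid_row = grid$grid_row[seq_along(v)],
             grid_col = grid$grid_col[seq_along(v)], score = v)
}

test_that("prediction maps place scores on the tile grid with validity mask", {
  m <- build_prediction_map(mk_scores(seq(0.1, 0.9, by = 0.1)), c(3, 3))
  expect_true(all(m$mask))
  expect_equal(mean(m$grid), mean(seq(0.1, 0.9, by = 0.1)))

  m8 <- build_prediction_map(mk_scores(seq(0.1, 0.8, by = 0.1)), c(3, 3))
  expect_equal(sum(!m8$mask), 1L)
  expect_equal(mean(m8$grid[m8$mask]), mean(seq(0.1, 0.8, by = 0.1)))

  dup <- rbind(mk_scores(0.5), mk_scores(0.6))
  expect_error(build_prediction_map(dup, c(3, 3)), "duplicate")
  out <- mk_scores(0.5)
  out$grid_row <- 4
  expect_error(build_prediction_map(out, c(3, 3)), "outside")
  two <- mk_scores(c(0.1, 0.2))
  two$cluster_id <- c("a", "b")
  expect_error(build_prediction_map(two, c(3, 3)), "single cluster")
})

test_that("heatmap features match brute-force statistics of the score list", {
  set.seed(13)
  for (trial in 1:200) {
    n <- sample(1:49, 1)
    v <- runif(n)
    dims <- c(7, 7)
    sc <- mk_scores(v, dims = dims)
    f <- extract_features(build_prediction_map(sc, dims))
    expect_equal(unclass(f)[names(brute_force_features(v))],
                 brute_force_features(v), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("degenerate feature inputs follow the declared conventions", {
  f1 <- extract_features(build_prediction_map(mk_scores(rep(1, 9)), c(3, 3)))
  expect_equal(unname(f1[c("mean", "max", "q50", "frac_gt_05")]), c(1, 1, 1, 1))
  expect_equal(unname(f1["sd"]), 0)

  f2 <- extract_features(build_prediction_map(mk_scores(c(0, 1)), c(3, 3)))
  expect_equal(unname(f2[c("mean", "frac_gt_05", "min", "max")]), c(0.5, 0.5, 0, 1))

  f3 <- extract_features(build_prediction_map(mk_scores(0.3), c(3, 3)))
  expect_equal(unname(f3[c("n_patches", "mean", "min", "max", "q10", "q90", "top5_mean")]),
               c(1, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3))
  expect_equal(unname(f3["sd"]), 0)

  empty_scores <- data.frame(cluster_id = character(0), grid_row = integer(0),
                             grid_col = integer(0), score = numeric(0))
  empty <- build_prediction_map(empty_scores, c(3, 3))
  expect_error(extract_features(empty), "empty-cluster")
})

test_that("combining features concatenates verbatim, color first", {
  fc <- extract_features(build_prediction_map(mk_scores(c(0.2, 0.4)), c(3, 3)), "color")
  fr <- extract_features(build_prediction_map(mk_scores(c(0.6, 0.8)), c(3, 3)), "ri")
  fb <- combine_features(fc, fr)
  expect_length(fb, 26L)
  expect_identical(names(fb), c(paste0("color_", names(fc)), paste0("ri_", names(fr))))
  expect_equal(unname(fb[paste0("color_", names(fc))]), as.numeric(fc))
  expect_equal(unname(fb[paste0("ri_", names(fr))]), as.numeric(fr))
  expect_identical(attr(fb, "modality"), "combined")

  other <- extract_features(build_prediction_map(mk_scores(0.1, id = "c2"), c(3, 3)), "ri")
  expect_error(combine_features(fc, other), "pairing")
})

test_that("cluster models train, predict probabilities and enforce the schema", {
  run <- small_run()$run
  feats <- run$features$combined
  truth <- run$cluster_truth
  labels <- truth$label[match(rownames(feats), truth$id)]

  model <- train_cluster_model(feats, labels, backend = "gbt", seed = 3)
  pred <- predict_clusters(model, feats)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_true(all(pred$label %in% c("benign", "malignant")))
  expect_identical(pred$label, ifelse(pred$score >= 0.5, "malignant", "benign"))

  dup <- predict_clusters(model, feats[c(1, 1), , drop = FALSE])
  expect_identical(dup$score[1], dup$score[2])

  wrong <- feats
  colnames(wrong)[1] <- "renamed"
  expect_error(predict_clusters(model, wrong), "schema")

  expect_error(train_cluster_model(feats, rep("benign", nrow(feats))),
               "unlearnable")
})

test_that("all four classifier backends fit and predict on one feature table", {
  skip_if_not_installed("randomForest")
  skip_if_not_installed("e1071")
  skip_if_not_installed("nnet")
  run <- small_run()$run
  feats <- run$features$combined
  truth <- run$cluster_truth
  labels <- truth$label[match(rownames(feats), truth$id)]
  tr <- truth$partition == "train"
  rows <- lapply(c("gbt", "rf", "svm", "mlp"), function(bk) {
    m <- train_cluster_model(feats[tr, , drop = FALSE], labels[tr],
                             backend = bk, seed = 4)
    p <- predict_clusters(m, feats[!tr, , drop = FALSE],
                          ids = rownames(feats)[!tr])
    expect_true(all(p$score >= 0 & p$score <= 1))
    cm <- confusion(labels[!tr], p$label)
    classification_metrics(cm)$accuracy
  })
  expect_length(rows, 4L)
  expect_true(all(unlist(rows) > 0.5))
})

test_that("permuted cluster labels give chance-level held-out accuracy", {
  run <- small_run()$run
  feats <- run$features$combined
  truth <- run$cluster_truth
  labels <- truth$label[match(rownames(feats), truth$id)]
  tr <- truth$partition == "train"
  set.seed(31)
  perm <- sample(labels[tr])
  m <- train_cluster_model(feats[tr, , drop = FALSE], perm, backend = "gbt", seed = 5)
  p <- predict_clusters(m, feats[!tr, , drop = FALSE], ids = rownames(feats)[!tr])
  acc <- classification_metrics(confusion(labels[!tr], p$label))$accuracy
  base <- max(mean(labels[!tr] == "benign"), mean(labels[!tr] == "malignant"))
  expect_lte(acc, base + 0.1)
})
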