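# A small separable two-class imaging task (dark blobs of two sizes) used to
# exercise the trainer contract without the full generator.
blob_inputs <- function(n_per_class, radius = c(2.2, 3.2), seed = 1, S = 16) {
  set.seed(seed)
  mk <- function(n, r) {
    t(vapply(seq_len(n), function(i) {
      m <- matrix(0.05, S, S)
      cx <- runif(1, 5, S - 4)
      cy <- runif(1, 5, S - 4)
      rr <- rnorm(1, r, 0.3)
      for (y in 1:S) {
        for (x in 1:S) {
          if ((x - cx)^2 + (y - cy)^2 < rr^2) m[y, x] <- 0.8
        }
      }
      as.vector(t(m)) + rnorm(S * S, 0, 0.04)
    }, numeric(S * S)))
  }
  x <- rbind(mk(n_per_class, radius[1]), mk(n_per_class, radius[2]))
  y <- rep(0:1, each = n_per_class)
  ord <- sample(nrow(x))
  info <- data.frame(cluster_id = "toy", grid_row = seq_len(nrow(x)),
                     grid_col = 1L,
                     label = ifelse(y[ord] == 1, "malignant", "benign"))
  cytofuse:::patch_inputs(x[ord, ], y[ord], info, "ri", 1L, S)
}

trained_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- blob_inputs(250, seed = 1)
      va <- blob_inputs(60, seed = 2)
      cache <<- list(
        tr = tr, va = va,
        model = train_patch_model(tr, va, patch_model_config("ri", epochs = 8, seed = 5))
      )
    }
    cache
  }
})

test_that("configuration validation catches modality and backbone problems", {
  expect_error(patch_model_config("color", input_channels = 1), "3 input channel")
  expect_error(patch_model_config("ri", input_channels = 3), "1 input channel")
  toy <- trained_toy()
  expect_error(
    train_patch_model(toy$tr, toy$va, patch_model_config("ri", backbone = "densenet169")),
    "unsupported backbone"
  )
  expect_error(
    train_patch_model(toy$tr, toy$va, patch_model_config("color", epochs = 1)),
    "modality"
  )
})

test_that("training learns a separable task and logs per-epoch losses", {
  toy <- trained_toy()
  m <- toy$model
  expect_s3_class(m, "patch_model")
  expect_equal(nrow(m$log), 8L)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_acc") %in% names(m$log)))
  expect_gte(m$log$val_acc[m$best_epoch], 0.85)
  expect_equal(m$best_epoch, which.min(m$log$val_loss))
})

test_that("training is bit-reproducible for a fixed seed", {
  tr <- blob_inputs(80, seed = 3)
  va <- blob_inputs(30, seed = 4)
  cfg <- patch_model_config("ri", epochs = 3, seed = 9)
  m1 <- train_patch_model(tr, va, cfg)
  m2 <- train_patch_model(tr, va, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$weights$wout, m2$weights$wout)
})

test_that("permuted labels stay inside the chance band", {
  tr <- blob_inputs(150, seed = 6)
  set.seed(8)
  tr$y <- sample(tr$y)
  tr$info$label <- ifelse(tr$y == 1, "malignant", "benign")
  va <- blob_inputs(60, seed = 7)
  m <- train_patch_model(tr, va, patch_model_config("ri", epochs = 5, seed = 2))
  expect_gte(m$log$val_acc[m$best_epoch], 0.3)
  expect_lte(m$log$val_acc[m$best_epoch], 0.7)
})

test_that("a single-class training set is an unlearnable task", {
  tr <- blob_inputs(40, seed = 10)
  keep <- tr$y == 1
  tr$x <- tr$x[keep, ]
  tr$y <- tr$y[keep]
  tr$info <- tr$info[keep, ]
  expect_error(train_patch_model(tr, blob_inputs(10, seed = 11),
                                 patch_model_config("ri")),
               "unlearnable")
})

test_that("scores are probabilities, pure and order-invariant", {
  toy <- trained_toy()
  sc <- score_patches(toy$model, toy$va)
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  rev_inputs <- toy$va
  rev_idx <- rev(seq_len(nrow(rev_inputs$x)))
  rev_inputs$x <- rev_inputs$x[rev_idx, ]
  rev_inputs$y <- rev_inputs$y[rev_idx]
  rev_inputs$info <- rev_inputs$info[rev_idx, ]
  sc_rev <- score_patches(toy$model, rev_inputs)
  expect_equal(rev(sc_rev$score), sc$score)

  dup <- toy$va
  dup$x <- dup$x[c(1, 1), ]
  dup$y <- dup$y[c(1, 1)]
  dup$info <- dup$info[c(1, 1), ]
  sd2 <- score_patches(toy$model, dup)
  expect_identical(sd2$score[1], sd2$score[2])

  wrong <- toy$va
  wrong$modality <- "color"
  wrong$channels <- 3L
  expect_error(score_patches(toy$model, wrong), "input error")
})

test_that("embeddings have constant dimension and identical rows for identical patches", {
  toy <- trained_toy()
  emb <- embed_patches(toy$model, toy$va)
  expect_equal(ncol(emb), 32L)
  expect_equal(nrow(emb), nrow(toy$va$x))
  dup <- toy$va
  dup$x <- dup$x[c(3, 3), ]
  dup$y <- dup$y[c(3, 3)]
  dup$info <- dup$info[c(3, 3), ]
  e2 <- embed_patches(toy$model, dup)
  expect_identical(e2[1, ], e2[2, ])
})

test_that("embedding space groups patches by class on synthetic data", {
  emb <- default_run(1)$embeddings
  d <- as.matrix(dist(emb$color))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gte(mean(emb$label[nn] == emb$label), 0.7)
})

test_that("each modality wins on the signal it carries", {
  # balanced-class study conditions isolating one class signal at a time:
  # equal detail -> only nucleus size separates (a color signal); equal size
  # -> only RI detail separates
  gaps_size <- numeric(0)
  gaps_detail <- numeric(0)
  for (sd in 1:3) {
    cfg_size <- generator_config(n_patients = 40, malignant_fraction = 0.5,
                                 detail_contrast_benign = 0.3,
                                 detail_contrast_malignant = 0.3001,
                                 seed = sd + 100)
    cfg_detail <- generator_config(n_patients = 40, malignant_fraction = 0.5,
                                   nucleus_radius_benign = c(mean = 4.0, sd = 0.6),
                                   nucleus_radius_malignant = c(mean = 4.05, sd = 0.6),
                                   seed = sd + 200)
    rs <- run_pipeline(cfg_size, seed = sd, embed_sample = 0)
    rd <- run_pipeline(cfg_detail, seed = sd, embed_sample = 0)
    pacc <- function(r, m) r$metrics$accuracy[r$metrics$level == "patch" &
                                                r$metrics$modality == m]
    gaps_size <- c(gaps_size, pacc(rs, "color") - pacc(rs, "ri"))
    gaps_detail <- c(gaps_detail, pacc(rd, "ri") - pacc(rd, "color"))
  }
  expect_gte(sum(gaps_size >= 0.05), 2)
  expect_gte(sum(gaps_detail >= 0.05), 2)
})
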