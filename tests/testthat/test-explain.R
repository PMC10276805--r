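test_that("Brenner gradient agrees with the naive double-loop oracle", {
  set.seed(17)
  for (i in 1:100) {
    img <- matrix(rnorm(32 * 32), 32, 32)
    expect_equal(brenner_gradient(img), naive_brenner(img), tolerance = 1e-9)
  }
  expect_identical(brenner_gradient(matrix(3.7, 8, 8)), 0)
  # 1-D ramp: horizontal two-pixel difference of 2 everywhere, vertical 0
  ramp <- matrix(rep(1:5, each = 5), 5, 5)
  expect_identical(brenner_gradient(ramp), 4)
  img <- matrix(runif(64), 8, 8)
  expect_equal(brenner_gradient(img + 11.3), brenner_gradient(img), tolerance = 1e-12)
  expect_error(brenner_gradient(matrix(0, 2, 10)), "at least 3 px")
})

test_that("score histograms use half-open bins with a closed top bin", {
  h <- score_histogram(c(0, 0.049))
  expect_equal(unname(h[1]), 2L)
  expect_equal(sum(h), 2L)
  h2 <- score_histogram(1.0)
  expect_equal(unname(h2[20]), 1L)
  expect_length(h2, 20L)
  set.seed(3)
  h3 <- score_histogram(runif(1000))
  expect_equal(sum(h3), 1000L)
  expect_error(score_histogram(c(0.5, 1.2)), "0, 1")
})

test_that("bin summaries sample at most 30 seeded patches per 0.2 bin", {
  scores <- c(rep(0.1, 10), rep(0.5, 60), 0.95)
  area <- seq_along(scores)
  bren <- rev(seq_along(scores))
  b1 <- bin_summaries(scores, area, bren, seed = 5)
  b2 <- bin_summaries(scores, area, bren, seed = 5)
  expect_identical(b1, b2)
  expect_equal(b1$n_in_bin, c(10L, 0L, 60L, 0L, 1L))
  expect_equal(b1$n_sampled, c(10L, 0L, 30L, 0L, 1L))
  expect_true(is.na(b1$mean_area_um2[2]))
  expect_equal(b1$mean_area_um2[1], mean(1:10))
  b3 <- bin_summaries(scores, area, bren, seed = 6)
  expect_false(identical(b1$sampled_ids[3], b3$sampled_ids[3]))
})

test_that("nucleus segmentation recovers a known disk and ignores blank fields", {
  blank <- matrix(0.5, 128, 128)
  seg0 <- segment_nuclei(blank, "ri")
  expect_equal(nrow(seg0$areas), 0L)
  expect_true(all(seg0$mask == 0L))

  pitch <- 26.1 / 256
  r_px <- 4 / pitch
  img <- matrix(0, 256, 256)
  for (y in 1:256) {
    for (x in 1:256) {
      if ((x - 128)^2 + (y - 128)^2 <= r_px^2) img[y, x] <- 1
    }
  }
  img <- img + matrix(rnorm(256^2, 0, 0.02), 256, 256)
  seg <- segment_nuclei(img, "ri")
  expect_equal(nrow(seg$areas), 1L)
  expect_lt(abs(seg$areas$area_um2[1] - pi * 16) / (pi * 16), 0.15)
  expect_equal(seg$areas$area_um2[1], sum(seg$mask == 1L) * pitch^2)
})

test_that("Grad-CAM maps are normalised, rectified and patch-sized", {
  sr <- small_run()
  model <- sr$run$models$color
  cl <- small_clusters()[[1]]   # malignant cluster
  ps <- filter_patches(tile_pair(cl))
  rich <- order(-vapply(ps$patches, function(p) sum(p$mask > 0), numeric(1)))[1:4]

  ratios <- vapply(rich, function(k) {
    sal <- grad_cam(model, ps$patches[[k]], "malignant")
    expect_true(all(sal$heat >= 0 & sal$heat <= 1))
    expect_equal(dim(sal$heat), c(256L, 256L))
    inside <- ps$patches[[k]]$mask > 0
    mean(sal$heat[inside]) / max(mean(sal$heat[!inside]), 1e-9)
  }, numeric(1))
  # saliency concentrates on nuclei rather than background
  expect_gt(mean(ratios > 1), 0.5)

  flat_model <- model
  flat_model$weights$wout <- rep(0, length(flat_model$weights$wout))
  expect_warning(sal0 <- grad_cam(flat_model, ps$patches[[rich[1]]], "malignant"),
                 "flat")
  expect_true(all(sal0$heat == 0))
})

test_that("t-SNE is seeded, collapses duplicates and validates inputs", {
  set.seed(23)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y1 <- tsne_embed(X, seed = 4, perplexity = 8, n_iter = 150)
  y2 <- tsne_embed(X, seed = 4, perplexity = 8, n_iter = 150)
  expect_identical(y1, y2)

  # duplicated rows land together: mutual nearest neighbours, close on the
  # layout scale (exact t-SNE equilibrates duplicate pairs at a few percent
  # of the coordinate range; reference exact implementations behave alike)
  Xd <- rbind(X, X[1, ])
  yd <- tsne_embed(Xd, seed = 4, perplexity = 12, n_iter = 500)
  d <- as.matrix(dist(yd))
  diag(d) <- Inf
  expect_equal(unname(which.min(d[1, ])), 41L)
  expect_equal(unname(which.min(d[41, ])), 1L)
  rng_max <- max(apply(yd, 2, function(cc) diff(range(cc))))
  expect_lt(d[1, 41], 0.1 * rng_max)

  expect_error(tsne_embed(X[1:5, ]), "at least 10")
  expect_error(tsne_embed(X, perplexity = 20), "perplexity")
})

test_that("joint color+RI embeddings separate the classes at least as well", {
  wins <- 0L
  for (sd in 1:5) {
    emb <- default_run(sd)$embeddings
    sil <- vapply(list(emb$color, emb$ri, cbind(emb$color, emb$ri)),
                  function(E) {
                    embedding_silhouette(tsne_embed(E, seed = 1, perplexity = 30),
                                         emb$label)
                  }, numeric(1))
    if (sil[3] >= max(sil[1], sil[2]) - 1e-9) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
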