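# End-to-end experiment driver: generate/stream clusters, tile and filter
# patches, split, train the two patch models, build heatmap features, train
# the cluster models (color / RI / combined) and evaluate both levels.

# Per-cluster streaming pass. Renders one cluster, tiles it on the
# block-mean-downsampled grid (exactly equivalent to tiling at full
# resolution and then block-averaging, since the stride is a multiple of the
# block factor), and computes per-patch metadata: pooled mean color, Brenner
# gradients of the RI channel and of the color luminance, and ground-truth
# nucleus statistics. Full-resolution images are dropped on return.
cluster_patch_pass <- function(sample, tiling = tiling_params(), input_size = 16) {
  ps <- tiling$patch_size
  st <- tiling$stride
  f <- ps %/% input_size
  stopifnot(f * input_size == ps, st %% f == 0)
  sst <- st %/% f
  H <- nrow(sample$ri_image)
  W <- ncol(sample$ri_image)
  dims <- tile_grid_dims(H, W, tiling)

  sc <- lapply(1:3, function(ch) block_mean(sample$color_image[, , ch], f))
  sri <- block_mean(sample$ri_image, f)
  I_bri <- brenner_integral_cpp(sample$ri_image)
  I_bcol <- brenner_integral_cpp(luminance_cpp(sample$color_image))
  core <- (ps - 2)^2

  n <- dims[1] * dims[2]
  info <- data.frame(
    cluster_id = rep(sample$cluster_id, n), patient_id = rep(sample$patient_id, n),
    label = rep(sample$label, n),
    grid_row = rep(seq_len(dims[1]), each = dims[2]),
    grid_col = rep(seq_len(dims[2]), times = dims[1]),
    y0 = 0L, x0 = 0L, mean_color = 0, kept = FALSE,
    brenner_ri = 0, brenner_color = 0, n_nuclei = 0L,
    nucleus_area_um2 = NA_real_, stringsAsFactors = FALSE
  )
  xcol <- matrix(0, n, 3 * input_size^2)
  xri <- matrix(0, n, input_size^2)
  pitch2 <- tiling$pixel_pitch^2

  k <- 0L
  for (r in seq_len(dims[1])) {
    for (cc in seq_len(dims[2])) {
      k <- k + 1L
      y0 <- (r - 1L) * st
      x0 <- (cc - 1L) * st
      ys <- ((r - 1L) * sst + 1L):((r - 1L) * sst + input_size)
      xs <- ((cc - 1L) * sst + 1L):((cc - 1L) * sst + input_size)
      wins <- lapply(sc, function(m) m[ys, xs])
      info$y0[k] <- y0
      info$x0[k] <- x0
      info$mean_color[k] <- mean(c(wins[[1]], wins[[2]], wins[[3]]))
      info$brenner_ri[k] <- window_sum(I_bri, y0, x0, ps - 2, ps - 2) / core
      info$brenner_color[k] <- window_sum(I_bcol, y0, x0, ps - 2, ps - 2) / core
      mwin <- sample$nucleus_mask[(y0 + 1):(y0 + ps), (x0 + 1):(x0 + ps)]
      if (any(mwin > 0L)) {
        cnt <- tabulate(mwin[mwin > 0L])
        cnt <- cnt[cnt > 0]
        info$n_nuclei[k] <- length(cnt)
        info$nucleus_area_um2[k] <- mean(cnt) * pitch2
      }
      xcol[k, ] <- flatten_maps(wins)  # raw block-mean counts
      xri[k, ] <- as.vector(t(sri[ys, xs]))
    }
  }
  info$kept <- info$mean_color >= tiling$color_mean_threshold
  list(info = info, xcol = xcol, xri = xri)
}

#' Run the full two-level classification experiment
#'
#' Generates the configured synthetic dataset cluster by cluster (one
#' cluster in memory at a time), tiles and filters patches, performs the
#' grouped stratified split, trains a color and an RI patch-level model,
#' scores every retained patch, aggregates scores into per-cluster heatmap
#' features, trains cluster-level models for the color, RI and combined
#' feature sets, and evaluates patch-level (test patches) and cluster-level
#' (eligible test clusters) performance.
#'
#' @param config A [generator_config()].
#' @param ratios Train/validation/test cluster ratios.
#' @param tiling A [tiling_params()].
#' @param input_size Downsampled side of the patch model input.
#' @param epochs,batch_size,learning_rate,filters Patch model training
#'   schedule (see [patch_model_config()]).
#' @param backend Cluster-model backend (see [train_cluster_model()]).
#' @param min_patches Eligibility threshold for cluster-level evaluation.
#' @param embed_sample Number of test patches (per modality) for which
#'   penultimate embeddings are retained, for downstream t-SNE analyses.
#' @param seed Seed for splitting, model training and sampling. The
#'   generator uses its own `config$seed`.
#' @param verbose Print progress.
#' @return An object of class `cf_run`: list with `manifest`, `split`,
#'   `patches` (per-patch metadata with `score_color` / `score_ri`),
#'   `features`, `predictions`, `metrics`, the trained `models` and
#'   `cluster_models`, `ri_norm` and the sampled `embeddings`.
#' @export
run_pipeline <- function(config,
                         ratios = c(0.64, 0.17, 0.19),
                         tiling = tiling_params(),
                         input_size = 16,
                         epochs = 10,
                         batch_size = 64,
                         learning_rate = 3e-3,
                         filters = c(8, 16, 32, 32),
                         backend = "gbt",
                         min_patches = 5,
                         embed_sample = 300,
                         seed = 1,
                         verbose = FALSE) {
  manifest <- dataset_manifest(config)
  split <- grouped_stratified_split(manifest[, c("cluster_id", "label")],
                                    ratios = ratios, seed = seed)

  if (verbose) message(sprintf("streaming %d clusters ...", nrow(manifest)))
  passes <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- render_cluster(config, manifest[i, ])
    cluster_patch_pass(s, tiling, input_size)
  })
  info <- do.call(rbind, lapply(passes, `[[`, "info"))
  keep <- info$kept
  xcol <- do.call(rbind, lapply(passes, `[[`, "xcol"))[keep, , drop = FALSE]
  xri_raw <- do.call(rbind, lapply(passes, `[[`, "xri"))[keep, , drop = FALSE]
  rm(passes)
  info <- info[keep, , drop = FALSE]
  rownames(info) <- NULL
  info$partition <- split$partition[match(info$cluster_id, split$cluster_id)]

  # dataset-level scaling constants from the training partition: RI is
  # min-max scaled; color becomes optical density relative to the median
  # background count
  tr <- info$partition == "train"
  va <- info$partition == "validation"
  te <- info$partition == "test"
  ri_norm <- c(min = min(xri_raw[tr, ]), max = max(xri_raw[tr, ]))
  xri <- (xri_raw - ri_norm[[1]]) / (ri_norm[[2]] - ri_norm[[1]])
  rm(xri_raw)
  color_norm <- c(bg = stats::median(xcol[tr, ]))
  xcol <- (color_norm[[1]] - xcol) / 255

  y <- as.integer(info$label == "malignant")
  mk_inputs <- function(x, rows, modality, channels) {
    patch_inputs(x[rows, , drop = FALSE], y[rows], info[rows, , drop = FALSE],
                 modality, channels, input_size,
                 norm = if (modality == "ri") ri_norm else color_norm)
  }

  if (verbose) message("training patch models ...")
  cfg_col <- patch_model_config("color", input_size = input_size, epochs = epochs,
                                batch_size = batch_size, learning_rate = learning_rate,
                                filters = filters, seed = derive_seed(seed, 101))
  cfg_ri <- patch_model_config("ri", input_size = input_size, epochs = epochs,
                               batch_size = batch_size, learning_rate = learning_rate,
                               filters = filters, seed = derive_seed(seed, 102))
  model_col <- train_patch_model(mk_inputs(xcol, tr, "color", 3L),
                                 mk_inputs(xcol, va, "color", 3L), cfg_col)
  model_ri <- train_patch_model(mk_inputs(xri, tr, "ri", 1L),
                                mk_inputs(xri, va, "ri", 1L), cfg_ri)

  all_rows <- rep(TRUE, nrow(info))
  info$score_color <- score_patches(model_col, mk_inputs(xcol, all_rows, "color", 3L))$score
  info$score_ri <- score_patches(model_ri, mk_inputs(xri, all_rows, "ri", 1L))$score

  # retain a seeded sample of test-patch embeddings for t-SNE analyses
  embeddings <- NULL
  te_idx <- which(te)
  if (embed_sample > 0 && length(te_idx) >= 10) {
    sel <- with_seed(derive_seed(seed, 103), {
      if (length(te_idx) > embed_sample) sample(te_idx, embed_sample) else te_idx
    })
    embeddings <- list(
      color = embed_patches(model_col, mk_inputs(xcol, sel, "color", 3L)),
      ri = embed_patches(model_ri, mk_inputs(xri, sel, "ri", 1L)),
      label = info$label[sel],
      index = sel
    )
  }
  rm(xcol, xri)

  if (verbose) message("cluster-level models ...")
  dims <- tile_grid_dims(config$image_size, config$image_size, tiling)
  feat_rows <- lapply(split(seq_len(nrow(info)), info$cluster_id), function(i) {
    sc <- info[i, ]
    fc <- extract_features(build_prediction_map(
      data.frame(cluster_id = sc$cluster_id, grid_row = sc$grid_row,
                 grid_col = sc$grid_col, score = sc$score_color), dims), "color")
    fr <- extract_features(build_prediction_map(
      data.frame(cluster_id = sc$cluster_id, grid_row = sc$grid_row,
                 grid_col = sc$grid_col, score = sc$score_ri), dims), "ri")
    list(color = fc, ri = fr, combined = combine_features(fc, fr),
         cluster_id = sc$cluster_id[1])
  })
  cluster_ids <- vapply(feat_rows, `[[`, character(1), "cluster_id")
  feat_mat <- function(tag) {
    m <- do.call(rbind, lapply(feat_rows, function(fr) as.numeric(fr[[tag]])))
    colnames(m) <- names(feat_rows[[1]][[tag]])
    rownames(m) <- cluster_ids
    m
  }
  feats <- lapply(c(color = "color", ri = "ri", combined = "combined"), feat_mat)

  ctruth <- data.frame(
    id = cluster_ids,
    label = manifest$label[match(cluster_ids, manifest$cluster_id)],
    n_patches = as.integer(table(info$cluster_id)[cluster_ids]),
    partition = split$partition[match(cluster_ids, split$cluster_id)],
    stringsAsFactors = FALSE
  )
  tr_cl <- ctruth$partition == "train"
  te_cl <- ctruth$partition == "test"

  cluster_models <- lapply(names(feats), function(tag) {
    train_cluster_model(feats[[tag]][tr_cl, , drop = FALSE],
                        ctruth$label[tr_cl], backend = backend,
                        seed = derive_seed(seed, 200 + match(tag, names(feats))))
  })
  names(cluster_models) <- names(feats)

  predictions <- do.call(rbind, lapply(names(feats), function(tag) {
    p <- predict_clusters(cluster_models[[tag]], feats[[tag]][te_cl, , drop = FALSE],
                          ids = ctruth$id[te_cl])
    data.frame(id = p$cluster_id, modality = tag, score = p$score, label = p$label,
               stringsAsFactors = FALSE)
  }))

  patch_pred <- do.call(rbind, lapply(c("color", "ri"), function(tag) {
    sc <- info[te, paste0("score_", tag)]
    data.frame(id = seq_along(sc), modality = tag,
               label = ifelse(sc >= 0.5, "malignant", "benign"),
               stringsAsFactors = FALSE)
  }))
  patch_truth <- data.frame(id = seq_len(sum(te)), label = info$label[te],
                            stringsAsFactors = FALSE)
  metrics <- rbind(
    evaluate_run(patch_pred, patch_truth, level = "patch"),
    evaluate_run(predictions[, c("id", "modality", "label")],
                 ctruth[, c("id", "label", "n_patches")],
                 level = "cluster", min_patches = min_patches)
  )

  structure(list(
    config = config, manifest = manifest, split = split, patches = info,
    features = feats, cluster_truth = ctruth, predictions = predictions,
    metrics = metrics, models = list(color = model_col, ri = model_ri),
    cluster_models = cluster_models, ri_norm = ri_norm, color_norm = color_norm,
    embeddings = embeddings, seed = seed
  ), class = "cf_run")
}

#' @export
print.cf_run <- function(x, ...) {
  cat(sprintf("cytofuse run: %d clusters, %d retained patches\n",
              nrow(x$manifest), nrow(x$patches)))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-8s %-9s n=%5d  accuracy %s\n", m$level[i], m$modality[i],
                m$n[i], format_metric(m$accuracy[i])))
  }
  invisible(x)
}
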