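#' Patch-level model configuration
#'
#' The desk-scale backbone is a small convolutional network (four 3x3 conv
#' blocks with ReLU, max-pooling after the early blocks, global average
#' pooling and a sigmoid head) trained with Adam on binary cross-entropy.
#' Patches are fed as block-mean-downsampled images of side `input_size`
#' (color: three channels as optical density relative to the dataset-median
#' background; RI: one channel, min-max scaled with dataset-level constants).
#' `"densenet169"` is accepted as a configuration value for fidelity with
#' large-scale training setups, but training it requires a deep-learning
#' runtime and raises an error here.
#'
#' @param modality `"color"` (3 input channels) or `"ri"` (1 channel).
#' @param backbone `"small_cnn"` or `"densenet169"`.
#' @param input_channels Defaults to 3 for color, 1 for RI; must match.
#' @param input_size Side of the downsampled model input in pixels; must
#'   divide the patch size.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param class_weighting Inverse-frequency loss weights for the ~73/27
#'   class imbalance.
#' @param augment Random horizontal/vertical flips (rotation-safe for
#'   cytology).
#' @param filters Filters of the four conv blocks.
#' @param deterministic Kept for interface compatibility; training is
#'   single-threaded and bit-reproducible for a given seed either way.
#' @param seed Master seed for weight init, shuffling and augmentation.
#' @return An object of class `patch_model_config`.
#' @export
patch_model_config <- function(modality = c("color", "ri"),
                               backbone = c("small_cnn", "densenet169"),
                               input_channels = NULL,
                               input_size = 16,
                               epochs = 10,
                               batch_size = 64,
                               learning_rate = 3e-3,
                               class_weighting = TRUE,
                               augment = TRUE,
                               filters = c(8, 16, 32, 32),
                               deterministic = TRUE,
                               seed = 1) {
  modality <- match.arg(modality)
  backbone <- match.arg(backbone)
  expected <- if (modality == "color") 3L else 1L
  if (is.null(input_channels)) input_channels <- expected
  if (input_channels != expected) {
    stop(sprintf("input error: modality '%s' requires %d input channel(s), got %d",
                 modality, expected, input_channels), call. = FALSE)
  }
  if (!(input_size %in% c(8, 16, 32, 64))) {
    stop("input_size must be one of 8, 16, 32, 64", call. = FALSE)
  }
  structure(list(modality = modality, backbone = backbone,
                 input_channels = as.integer(input_channels),
                 input_size = as.integer(input_size),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 class_weighting = isTRUE(class_weighting),
                 augment = isTRUE(augment),
                 filters = as.integer(filters),
                 deterministic = isTRUE(deterministic),
                 seed = as.integer(seed)),
            class = "patch_model_config")
}

# Internal constructor for the matrix-of-rows input container used by the
# trainer and scorer. Row layout: channel-major, then row (y), then column.
patch_inputs <- function(x, y, info, modality, channels, input_size, norm = NULL) {
  structure(list(x = x, y = y, info = info, modality = modality,
                 channels = as.integer(channels), input_size = as.integer(input_size),
                 norm = norm),
            class = "patch_inputs")
}

flatten_maps <- function(mats) {
  # mats: list of S x S matrices (one per channel) -> one row vector
  unlist(lapply(mats, function(m) as.vector(t(m))), use.names = FALSE)
}

#' Convert patches to model inputs
#'
#' Downsamples each patch by block averaging to `input_size` and scales it:
#' color counts become optical density relative to the dataset-median
#' background count; RI values are min-max scaled. Both use dataset-level
#' constants (`norm`), computed from the supplied patches when not provided
#' and recorded in the result so validation/test data can reuse the training
#' constants.
#'
#' @param patch_set A [tile_pair()] result (optionally filtered).
#' @param modality `"color"` or `"ri"`.
#' @param input_size Downsampled side length.
#' @param norm Optional scaling constants: `c(bg = )` for color,
#'   `c(min, max)` for RI.
#' @return A `patch_inputs` object.
#' @export
prepare_patch_inputs <- function(patch_set, modality = c("color", "ri"),
                                 input_size = 16, norm = NULL) {
  modality <- match.arg(modality)
  ps <- patch_set$params$patch_size
  f <- ps %/% input_size
  stopifnot(f * input_size == ps)
  if (modality == "color") {
    # optical-density representation: background-subtracted and inverted, so
    # stained structures are positive on a ~0 background. The background
    # level is the dataset-level median count, recorded in `norm`.
    raw <- lapply(patch_set$patches, function(p) {
      lapply(1:3, function(ch) block_mean(p$color[, , ch], f))
    })
    if (is.null(norm)) {
      norm <- c(bg = stats::median(unlist(raw)))
    }
    rows <- lapply(raw, function(chs) {
      flatten_maps(lapply(chs, function(m) (norm[[1]] - m) / 255))
    })
    channels <- 3L
  } else {
    small <- lapply(patch_set$patches, function(p) block_mean(p$ri, f))
    if (is.null(norm)) {
      rng <- range(unlist(lapply(small, range)))
      norm <- c(min = rng[1], max = max(rng[2], rng[1] + 1e-9))
    }
    rows <- lapply(small, function(m) {
      as.vector(t((m - norm[[1]]) / (norm[[2]] - norm[[1]])))
    })
    channels <- 1L
  }
  y <- as.integer(patch_set$info$label == "malignant")
  patch_inputs(do.call(rbind, rows), y, patch_set$info, modality, channels,
               input_size, norm)
}

#' Train a patch-level malignancy classifier
#'
#' Fits the configured backbone on training patches, selecting the epoch
#' with the lowest validation loss. The per-epoch training log is retained.
#'
#' @param train_inputs,val_inputs `patch_inputs` (see
#'   [prepare_patch_inputs()]); both non-empty, single modality.
#' @param config A [patch_model_config()].
#' @return An object of class `patch_model`: weights, config, training
#'   `log`, `best_epoch`, RI normalization constants, and the class mapping
#'   (score = probability of `"malignant"`).
#' @export
train_patch_model <- function(train_inputs, val_inputs, config = patch_model_config()) {
  stopifnot(inherits(train_inputs, "patch_inputs"), inherits(val_inputs, "patch_inputs"))
  if (config$backbone == "densenet169") {
    stop("unsupported backbone: 'densenet169' requires a deep-learning runtime; ",
         "use backbone = 'small_cnn'", call. = FALSE)
  }
  if (train_inputs$modality != config$modality) {
    stop("input error: training data modality does not match the configuration", call. = FALSE)
  }
  if (nrow(train_inputs$x) == 0 || nrow(val_inputs$x) == 0) {
    stop("input error: training and validation sets must be non-empty", call. = FALSE)
  }
  if (length(unique(train_inputs$y)) < 2) {
    stop("unlearnable task: training set contains a single class", call. = FALSE)
  }
  S <- train_inputs$input_size
  C <- train_inputs$channels
  stopifnot(ncol(train_inputs$x) == C * S * S, ncol(val_inputs$x) == C * S * S)
  fit <- cnn_train_cpp(train_inputs$x, train_inputs$y, val_inputs$x, val_inputs$y,
                       C, S, config$filters, config$epochs, config$batch_size,
                       config$learning_rate, config$class_weighting,
                       config$augment, config$seed)
  structure(list(
    weights = fit[c("W", "b", "wout", "bout", "C", "S", "filters")],
    config = config,
    log = fit$log,
    best_epoch = fit$best_epoch,
    best_val_loss = fit$best_val_loss,
    norm = train_inputs$norm,
    classes = c(negative = "benign", positive = "malignant")
  ), class = "patch_model")
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf("patch_model (%s, %s): input %dx%dx%d, best epoch %d (val loss %.4f)\n",
              x$config$backbone, x$config$modality, x$weights$C, x$weights$S,
              x$weights$S, x$best_epoch, x$best_val_loss))
  invisible(x)
}

check_model_inputs <- function(model, inputs) {
  stopifnot(inherits(model, "patch_model"), inherits(inputs, "patch_inputs"))
  if (inputs$channels != model$weights$C || inputs$input_size != model$weights$S) {
    stop(sprintf("input error: model expects %d channel(s) at %d px, got %d at %d px",
                 model$weights$C, model$weights$S, inputs$channels, inputs$input_size),
         call. = FALSE)
  }
  if (inputs$modality != model$config$modality) {
    stop("input error: patch modality does not match the model", call. = FALSE)
  }
}

#' Score patches with a trained model
#'
#' @param model A [train_patch_model()] result.
#' @param inputs `patch_inputs` of the same modality.
#' @return A data.frame: the input's `info` columns plus `score`, the
#'   probability in \[0,1\] that the patch came from a malignant cluster.
#' @export
score_patches <- function(model, inputs) {
  check_model_inputs(model, inputs)
  fw <- cnn_forward_cpp(model$weights, inputs$x)
  out <- inputs$info
  out$score <- pmin(pmax(as.numeric(fw$prob), 0), 1)
  out
}

#' Penultimate-layer embeddings of patches
#'
#' Returns the global-average-pooled activations of the final conv block,
#' one fixed-length vector per patch (the representation fed to t-SNE).
#'
#' @inheritParams score_patches
#' @return A numeric matrix, one row per patch.
#' @export
embed_patches <- function(model, inputs) {
  check_model_inputs(model, inputs)
  fw <- cnn_forward_cpp(model$weights, inputs$x)
  emb <- fw$embedding
  rownames(emb) <- NULL
  emb
}
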