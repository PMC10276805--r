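#' Assemble a per-cluster malignancy prediction map
#'
#' Arranges one cluster's patch scores on the tiling grid ("heatmap"). Grid
#' cells whose patch was filtered out (or never scored) are marked invalid.
#'
#' @param scores A data.frame with `cluster_id`, `grid_row`, `grid_col`,
#'   `score`, all sharing one `cluster_id`.
#' @param dims Integer `c(rows, cols)` of the tiling grid.
#' @return An object of class `prediction_map`: list with `cluster_id`,
#'   `grid` (rows x cols, NA where invalid), `mask` (logical validity).
#' @export
build_prediction_map <- function(scores, dims) {
  stopifnot(all(c("cluster_id", "grid_row", "grid_col", "score") %in% names(scores)))
  if (length(unique(scores$cluster_id)) > 1) {
    stop("data-integrity error: scores must come from a single cluster", call. = FALSE)
  }
  if (anyDuplicated(scores[, c("grid_row", "grid_col")])) {
    stop("data-integrity error: duplicate grid positions in scores", call. = FALSE)
  }
  if (any(scores$grid_row < 1 | scores$grid_row > dims[1] |
          scores$grid_col < 1 | scores$grid_col > dims[2])) {
    stop("data-integrity error: grid position outside the tiling grid", call. = FALSE)
  }
  grid <- matrix(NA_real_, dims[1], dims[2])
  grid[cbind(scores$grid_row, scores$grid_col)] <- scores$score
  structure(list(cluster_id = scores$cluster_id[1], grid = grid, mask = !is.na(grid)),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("prediction_map %s: %d x %d grid, %d valid patches\n",
              x$cluster_id, nrow(x$grid), ncol(x$grid), sum(x$mask)))
  invisible(x)
}

#' Heatmap features of a prediction map
#'
#' Summarises the valid cells of a cluster's prediction map with order
#' statistics (mean, sd, min, max, five quantiles), exceedance fractions
#' (scores strictly above 0.5 and 0.9), the mean of the top five scores
#' (all scores when fewer than five) and the patch count. The feature set is
#' versioned through the names; the combined model concatenates the two
#' modalities' vectors.
#'
#' @param map A [build_prediction_map()] result.
#' @param modality Tag recorded on the result.
#' @return A named numeric vector of 13 features with attributes
#'   `cluster_id` and `modality`.
#' @export
extract_features <- function(map, modality = "color") {
  stopifnot(inherits(map, "prediction_map"))
  v <- map$grid[map$mask]
  if (length(v) == 0) {
    stop("empty-cluster error: prediction map has no valid cells", call. = FALSE)
  }
  q <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  out <- c(
    n_patches = length(v),
    mean = mean(v),
    sd = if (length(v) > 1) sd(v) else 0,
    min = min(v),
    max = max(v),
    q10 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q90 = q[5],
    frac_gt_05 = mean(v > 0.5),
    frac_gt_09 = mean(v > 0.9),
    top5_mean = mean(sort(v, decreasing = TRUE)[seq_len(min(5, length(v)))])
  )
  attr(out, "cluster_id") <- map$cluster_id
  attr(out, "modality") <- modality
  out
}

#' Concatenate color and RI features for the combined model
#'
#' Color features come first, then RI, each value kept verbatim under a
#' modality-prefixed name; the result is tagged `"combined"`.
#'
#' @param color,ri [extract_features()] vectors for the same cluster.
#' @return A named numeric vector with attributes `cluster_id`, `modality`.
#' @export
combine_features <- function(color, ri) {
  if (!identical(attr(color, "cluster_id"), attr(ri, "cluster_id"))) {
    stop("pairing error: features come from different clusters", call. = FALSE)
  }
  out <- c(stats::setNames(as.numeric(color), paste0("color_", names(color))),
           stats::setNames(as.numeric(ri), paste0("ri_", names(ri))))
  attr(out, "cluster_id") <- attr(color, "cluster_id")
  attr(out, "modality") <- "combined"
  out
}

#' Train the cluster-level classifier
#'
#' Fits a tree ensemble (gradient-boosted trees by default; the capacity is
#' kept small for few-cluster datasets) on heatmap features. Random-forest,
#' support-vector-machine and multi-layer-perceptron backends are available
#' for robustness comparisons.
#'
#' @param features Numeric matrix or data.frame, one row per cluster.
#' @param labels `"benign"`/`"malignant"` per row.
#' @param backend One of `"gbt"`, `"rf"`, `"svm"`, `"mlp"`.
#' @param seed Integer seed.
#' @param nrounds,max_depth,eta Gradient-boosting capacity (gbt backend).
#' @return An object of class `cluster_model`.
#' @export
train_cluster_model <- function(features, labels, backend = c("gbt", "rf", "svm", "mlp"),
                                seed = 1, nrounds = 150, max_depth = 3, eta = 0.1) {
  backend <- match.arg(backend)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("unlearnable task: a single class is present", call. = FALSE)
  }
  y <- as.integer(labels == "malignant")
  fit <- with_seed(seed, switch(backend,
    gbt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = nrounds
    ),
    rf = {
      requireNamespace("randomForest", quietly = TRUE) ||
        stop("backend 'rf' needs the randomForest package", call. = FALSE)
      randomForest::randomForest(x = X, y = factor(labels, c("benign", "malignant")),
                                 ntree = 300)
    },
    svm = {
      requireNamespace("e1071", quietly = TRUE) ||
        stop("backend 'svm' needs the e1071 package", call. = FALSE)
      e1071::svm(x = X, y = factor(labels, c("benign", "malignant")),
                 probability = TRUE, kernel = "radial")
    },
    mlp = {
      requireNamespace("nnet", quietly = TRUE) ||
        stop("backend 'mlp' needs the nnet package", call. = FALSE)
      ctr <- apply(X, 2, mean)
      scl <- pmax(apply(X, 2, sd), 1e-8)
      Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      m <- nnet::nnet(Xs, y, size = 8, decay = 1e-3, maxit = 400, trace = FALSE)
      list(net = m, center = ctr, scale = scl)
    }
  ))
  structure(list(backend = backend, fit = fit, feature_names = colnames(X),
                 seed = seed),
            class = "cluster_model")
}

#' Predict cluster malignancy
#'
#' @param model A [train_cluster_model()] result.
#' @param features Numeric matrix/data.frame with the training feature
#'   schema; row names (or a `cluster_id` attribute column) identify
#'   clusters.
#' @param ids Optional cluster identifiers (defaults to row names).
#' @return A data.frame with `cluster_id`, `score` in \[0,1\] and `label`
#'   (`"malignant"` when `score >= 0.5`).
#' @export
predict_clusters <- function(model, features, ids = rownames(features)) {
  stopifnot(inherits(model, "cluster_model"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!identical(colnames(X), model$feature_names)) {
    stop("input error: feature schema does not match the trained model", call. = FALSE)
  }
  score <- switch(model$backend,
    gbt = predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    rf = predict(model$fit, X, type = "prob")[, "malignant"],
    svm = {
      p <- predict(model$fit, X, probability = TRUE)
      attr(p, "probabilities")[, "malignant"]
    },
    mlp = {
      Xs <- sweep(sweep(X, 2, model$fit$center), 2, model$fit$scale, "/")
      as.numeric(predict(model$fit$net, Xs))
    }
  )
  score <- pmin(pmax(as.numeric(score), 0), 1)
  data.frame(cluster_id = if (is.null(ids)) seq_len(nrow(X)) else ids,
             score = score,
             label = ifelse(score >= 0.5, "malignant", "benign"),
             stringsAsFactors = FALSE)
}
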