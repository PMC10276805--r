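#' Brenner gradient of a single-channel image
#'
#' Squared two-pixel forward-difference focus/detail measure: the mean over
#' the interior region (both shifts defined) of
#' `(I(y, x+2) - I(y, x))^2 + (I(y+2, x) - I(y, x))^2`. The mean (rather
#' than sum) normalisation makes values comparable across patch sizes; the
#' measure is invariant to adding a constant.
#'
#' @param img Numeric matrix, at least 3 pixels in each dimension.
#' @return A single non-negative number.
#' @export
brenner_gradient <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  H <- nrow(img)
  W <- ncol(img)
  if (H < 3 || W < 3) {
    stop("input error: image must be at least 3 px in each dimension", call. = FALSE)
  }
  core <- img[1:(H - 2), 1:(W - 2), drop = FALSE]
  dh <- img[1:(H - 2), 3:W, drop = FALSE] - core
  dv <- img[3:H, 1:(W - 2), drop = FALSE] - core
  mean(dh^2 + dv^2)
}

# Per-pixel Brenner field (interior grid), used for fast windowed means.
brenner_field <- function(img) {
  H <- nrow(img)
  W <- ncol(img)
  core <- img[1:(H - 2), 1:(W - 2), drop = FALSE]
  (img[1:(H - 2), 3:W, drop = FALSE] - core)^2 +
    (img[3:H, 1:(W - 2), drop = FALSE] - core)^2
}

#' Histogram of patch prediction scores
#'
#' Fixed-width bins over \[0, 1\]: `[k*w, (k+1)*w)` with the last bin closed
#' at 1. Counts always conserve the number of scores.
#'
#' @param scores Numeric vector in \[0, 1\].
#' @param bin_width Bin width; `1/bin_width` must be an integer.
#' @return A named integer vector of counts, class `score_histogram`.
#' @export
score_histogram <- function(scores, bin_width = 0.05) {
  if (any(scores < 0 | scores > 1)) {
    stop("input error: scores must lie in [0, 1]", call. = FALSE)
  }
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9) {
    stop("input error: 1/bin_width must be an integer", call. = FALSE)
  }
  idx <- pmin(floor(scores / bin_width), nb - 1) + 1
  counts <- tabulate(idx, nbins = nb)
  lo <- (seq_len(nb) - 1) * bin_width
  names(counts) <- sprintf("[%.2f,%.2f%s", lo, lo + bin_width,
                           c(rep(")", nb - 1), "]"))
  structure(as.integer(counts), names = names(counts), class = "score_histogram")
}

#' Per-score-bin image characteristics
#'
#' Groups patches by prediction score into fixed-width bins (0.2 by
#' default), samples up to `n_per_bin` patches per bin without replacement
#' under the seed, and reports the mean nucleus area and mean Brenner
#' gradient of the sampled patches. Empty bins report `n_sampled = 0` and
#' missing means; patches without any nucleus contribute no area value.
#'
#' @param scores Numeric vector of patch scores in \[0, 1\].
#' @param nucleus_area Per-patch mean nucleus area in um^2 (`NA` when the
#'   patch contains no nucleus), aligned with `scores`.
#' @param brenner Per-patch Brenner gradient, aligned with `scores`.
#' @param bin_width Bin width partitioning \[0, 1\].
#' @param n_per_bin Maximum patches sampled per bin.
#' @param seed Sampling seed.
#' @param patch_id Optional identifiers recorded for the sampled patches.
#' @return A data.frame with one row per bin: `bin_lo`, `bin_hi`, `n_in_bin`,
#'   `n_sampled`, `mean_area_um2`, `mean_brenner`, `sampled_ids`.
#' @export
bin_summaries <- function(scores, nucleus_area, brenner, bin_width = 0.2,
                          n_per_bin = 30, seed = 1, patch_id = NULL) {
  stopifnot(length(scores) == length(nucleus_area),
            length(scores) == length(brenner))
  nb <- round(1 / bin_width)
  idx <- pmin(floor(scores / bin_width), nb - 1) + 1
  if (is.null(patch_id)) patch_id <- as.character(seq_along(scores))
  rows <- with_seed(seed, lapply(seq_len(nb), function(b) {
    members <- which(idx == b)
    take <- if (length(members) > n_per_bin) {
      sample(members, n_per_bin)
    } else {
      members
    }
    data.frame(
      bin_lo = (b - 1) * bin_width,
      bin_hi = b * bin_width,
      n_in_bin = length(members),
      n_sampled = length(take),
      mean_area_um2 = if (length(take) && any(!is.na(nucleus_area[take]))) {
        mean(nucleus_area[take], na.rm = TRUE)
      } else NA_real_,
      mean_brenner = if (length(take)) mean(brenner[take]) else NA_real_,
      sampled_ids = paste(patch_id[take], collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  do.call(rbind, rows)
}

#' Threshold-based nucleus segmentation of a patch
#'
#' Otsu global thresholding of the nucleus-signal channel (inverted
#' luminance for color patches; the raw channel for RI patches), connected
#' components, and a minimum-size filter. Intended for measuring nuclear
#' areas when no ground-truth mask is available.
#'
#' @param image For `modality = "color"` an H x W x 3 array of 8-bit counts;
#'   for `"ri"` an H x W matrix.
#' @param modality `"color"` or `"ri"`.
#' @param pixel_pitch Micrometres per pixel.
#' @param min_area_um2 Components smaller than this are discarded.
#' @return A list with `mask` (integer label map, 0 = background) and
#'   `areas` (data.frame `nucleus`, `area_um2`); both empty when nothing
#'   qualifies.
#' @export
segment_nuclei <- function(image, modality = c("color", "ri"),
                           pixel_pitch = 26.1 / 256, min_area_um2 = 2) {
  modality <- match.arg(modality)
  signal <- if (modality == "color") {
    (255 - luminance(image)) / 255
  } else {
    image
  }
  rng <- range(signal)
  empty <- list(mask = matrix(0L, nrow(signal), ncol(signal)),
                areas = data.frame(nucleus = integer(0), area_um2 = numeric(0)))
  if (diff(rng) < 1e-9) return(empty)
  signal <- (signal - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(signal), range = c(0, 1))
  bw <- signal > th
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  min_px <- ceiling(min_area_um2 / pixel_pitch^2)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_px)
  if (length(keep) == 0) return(empty)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  mask <- matrix(0L, nrow(signal), ncol(signal))
  pos <- lab > 0
  mask[pos] <- relab[lab[pos]]
  list(mask = mask,
       areas = data.frame(nucleus = seq_along(keep),
                          area_um2 = counts[keep] * pixel_pitch^2))
}

#' Grad-CAM saliency map for a patch
#'
#' Gradient-weighted class activation mapping on the final conv block of the
#' patch model: channel weights are the spatially averaged gradients of the
#' target-class logit with respect to the block's activations, the weighted
#' activation sum is rectified, bilinearly upsampled to the patch size, and
#' max-normalised to 1. A patch producing an all-zero map (no positively
#' contributing activation) yields a flat map with a warning.
#'
#' @param model A [train_patch_model()] result.
#' @param patch One patch of a [tile_pair()] result (list with `color`
#'   and/or `ri` pixels at full resolution).
#' @param target_class `"malignant"` or `"benign"`.
#' @param out_size Side of the upsampled map (defaults to the patch size).
#' @return A list of class `saliency_map`: `heat` (out_size x out_size in
#'   \[0,1\]), `target`, `modality`.
#' @export
grad_cam <- function(model, patch, target_class = c("malignant", "benign"),
                     out_size = NULL) {
  target_class <- match.arg(target_class)
  stopifnot(inherits(model, "patch_model"))
  modality <- model$config$modality
  S <- model$weights$S
  if (modality == "color") {
    px <- patch$color
    stopifnot(length(dim(px)) == 3)
    f <- dim(px)[1] %/% S
    bg <- if (!is.null(model$norm)) model$norm[[1]] else 200
    row <- flatten_maps(lapply(1:3, function(ch) (bg - block_mean(px[, , ch], f)) / 255))
    full <- dim(px)[1]
  } else {
    px <- patch$ri
    stopifnot(is.matrix(px))
    f <- nrow(px) %/% S
    m <- block_mean(px, f)
    if (!is.null(model$norm)) m <- (m - model$norm[[1]]) / (model$norm[[2]] - model$norm[[1]])
    row <- as.vector(t(m))
    full <- nrow(px)
  }
  if (is.null(out_size)) out_size <- full
  heat_small <- cnn_gradcam_cpp(model$weights, matrix(row, nrow = 1),
                                as.integer(target_class == "malignant"))
  if (max(heat_small) <= 0) {
    warning("all-zero gradient field; returning a flat saliency map")
    heat <- matrix(0, out_size, out_size)
  } else {
    heat <- EBImage::imageData(EBImage::resize(EBImage::Image(heat_small),
                                               w = out_size, h = out_size))
    heat <- pmax(heat, 0)
    heat <- heat / max(heat)
  }
  structure(list(heat = heat, target = target_class, modality = modality),
            class = "saliency_map")
}

#' Exact t-SNE embedding of patch representations
#'
#' Standard t-distributed stochastic neighbour embedding with per-point
#' perplexity calibration (binary search on the Gaussian bandwidth), early
#' exaggeration and momentum gradient descent; exact O(n^2) pairwise
#' computation, deterministic under the seed. For a combined-modality view,
#' concatenate the per-patch color and RI embedding vectors before calling.
#'
#' @param embeddings Numeric matrix, one row per patch (n >= 10).
#' @param seed Integer seed for the initial layout.
#' @param perplexity Effective neighbourhood size; must be `< n/3`.
#' @param n_iter Gradient-descent iterations.
#' @return An n x 2 matrix of coordinates.
#' @export
tsne_embed <- function(embeddings, seed = 1, perplexity = 30, n_iter = 400) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (n < 10) stop("input error: need at least 10 embeddings", call. = FALSE)
  if (perplexity >= n / 3) {
    stop("input error: perplexity must be smaller than n/3", call. = FALSE)
  }
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf
    hi <- Inf
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) {
        h <- 0
      } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) {  # entropy too high -> narrow the kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  vel <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  # learning rate grows with n, clamped to the classic value of 200; the
  # descent diverges for very small n at the classic rate
  eta <- min(max(n, 50), 200)
  for (iter in seq_len(n_iter)) {
    mom <- if (iter <= 250) 0.5 else 0.8
    Pit <- if (iter <= 100) P * 12 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    G <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    gains <- pmax(0.01, ifelse(sign(G) != sign(vel), gains + 0.2, gains * 0.8))
    vel <- mom * vel - eta * gains * G
    Y <- Y + vel
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Mean silhouette width of class labels on a 2-D embedding
#'
#' Convenience wrapper used to compare how distinctly two classes separate
#' in t-SNE layouts of different modalities.
#'
#' @param coords n x 2 coordinate matrix.
#' @param labels Class labels, length n.
#' @return Mean silhouette width.
#' @export
embedding_silhouette <- function(coords, labels) {
  cl <- as.integer(factor(labels))
  if (requireNamespace("cluster", quietly = TRUE)) {
    mean(cluster::silhouette(cl, stats::dist(coords))[, "sil_width"])
  } else {
    d <- as.matrix(stats::dist(coords))
    s <- vapply(seq_along(cl), function(i) {
      same <- setdiff(which(cl == cl[i]), i)
      if (length(same) == 0) return(0)
      a <- mean(d[i, same])
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(k) mean(d[i, cl == k]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
}
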