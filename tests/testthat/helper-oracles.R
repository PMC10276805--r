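# Independent brute-force oracles used to check the package's fast paths.

# Enumerate fully contained windows one offset at a time.
brute_force_tile_count <- function(height, width, patch_size = 256, stride = 128) {
  n_rows <- 0L
  y0 <- 0L
  while (y0 + patch_size <= height) {
    n_rows <- n_rows + 1L
    y0 <- y0 + stride
  }
  n_cols <- 0L
  x0 <- 0L
  while (x0 + patch_size <= width) {
    n_cols <- n_cols + 1L
    x0 <- x0 + stride
  }
  n_rows * n_cols
}

# Naive double-loop Brenner gradient (two-pixel forward differences).
naive_brenner <- function(img) {
  H <- nrow(img)
  W <- ncol(img)
  acc <- 0
  n <- 0
  for (y in 1:(H - 2)) {
    for (x in 1:(W - 2)) {
      acc <- acc + (img[y, x + 2] - img[y, x])^2 + (img[y + 2, x] - img[y, x])^2
      n <- n + 1
    }
  }
  acc / n
}

# Direct statistics of a score vector, mirroring the heatmap feature set.
brute_force_features <- function(v) {
  q <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  c(n_patches = length(v), mean = mean(v),
    sd = if (length(v) > 1) sd(v) else 0,
    min = min(v), max = max(v),
    q10 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q90 = q[5],
    frac_gt_05 = mean(v > 0.5), frac_gt_09 = mean(v > 0.9),
    top5_mean = mean(sort(v, decreasing = TRUE)[seq_len(min(5, length(v)))]))
}

# A minimal in-memory patch_set with constant-valued patches, for filter and
# feature tests that need no rendered imagery.
toy_patch_set <- function(color_values, patch_size = 8) {
  patches <- lapply(color_values, function(v) {
    list(color = array(v, dim = c(patch_size, patch_size, 3)),
         ri = matrix(0, patch_size, patch_size))
  })
  info <- data.frame(
    cluster_id = "toy", grid_row = seq_along(color_values), grid_col = 1L,
    y0 = 0L, x0 = 0L,
    mean_color = vapply(patches, function(p) mean(p$color), numeric(1)),
    label = "benign", stringsAsFactors = FALSE
  )
  structure(list(patches = patches, info = info,
                 params = tiling_params(patch_size = patch_size,
                                        stride = patch_size)),
            class = "patch_set")
}
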