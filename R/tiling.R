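#' Tiling parameters
#'
#' Clusters are analysed as overlapping square patches: 256 x 256 pixels
#' (26.1 um x 26.1 um at the default pitch) with a 128-pixel stride, and a
#' patch is retained when the arithmetic mean of its color image counts
#' (all pixels, all three channels pooled) is at least 170.
#'
#' @param patch_size Patch side in pixels.
#' @param stride Offset between adjacent patch origins, `0 < stride <= patch_size`.
#' @param color_mean_threshold Inclusion threshold on the pooled mean color
#'   count, in \[0, 255\].
#' @param pixel_pitch Micrometres per pixel.
#' @return An object of class `tiling_params`.
#' @export
tiling_params <- function(patch_size = 256, stride = 128,
                          color_mean_threshold = 170, pixel_pitch = 26.1 / 256) {
  if (stride <= 0 || stride > patch_size) {
    stop("invalid tiling parameters: need 0 < stride <= patch_size", call. = FALSE)
  }
  if (color_mean_threshold < 0 || color_mean_threshold > 255) {
    stop("invalid tiling parameters: threshold must be in [0, 255]", call. = FALSE)
  }
  structure(list(patch_size = as.integer(patch_size), stride = as.integer(stride),
                 color_mean_threshold = color_mean_threshold,
                 pixel_pitch = pixel_pitch),
            class = "tiling_params")
}

#' Tile grid dimensions for an image
#'
#' Number of patch rows and columns: windows start at every multiple of the
#' stride and must lie fully inside the image (no padding, no extra
#' edge-anchored window), i.e. `floor((H - patch_size)/stride) + 1` per axis.
#'
#' @param height,width Image dimensions in pixels.
#' @param params A [tiling_params()].
#' @return Integer vector `c(rows, cols)`.
#' @export
tile_grid_dims <- function(height, width, params = tiling_params()) {
  if (height < params$patch_size || width < params$patch_size) {
    stop(sprintf("image (%d x %d) is smaller than the patch size (%d): no patches can be produced",
                 height, width, params$patch_size), call. = FALSE)
  }
  c(rows = as.integer((height - params$patch_size) %/% params$stride + 1L),
    cols = as.integer((width - params$patch_size) %/% params$stride + 1L))
}

#' Cut a cluster's registered image pair into patches
#'
#' Both modalities are cropped identically; patches are emitted in row-major
#' grid order. Grid indices are 1-based; `y0`/`x0` are the 0-based top-left
#' pixel offsets of the half-open window `[y0, y0 + patch_size)`.
#'
#' @param sample A `cluster_sample` (or any list with `color_image`,
#'   `ri_image`, `cluster_id`, `label`, optionally `nucleus_mask`).
#' @param params A [tiling_params()].
#' @return An object of class `patch_set`: list with `patches` (each with
#'   `color`, `ri`, optionally `mask`) and `info` (one row per patch:
#'   `cluster_id`, `grid_row`, `grid_col`, `y0`, `x0`, `mean_color`, `label`).
#' @export
tile_pair <- function(sample, params = tiling_params()) {
  H <- dim(sample$ri_image)[1]
  W <- dim(sample$ri_image)[2]
  stopifnot(all(dim(sample$color_image)[1:2] == c(H, W)))
  dims <- tile_grid_dims(H, W, params)
  ps <- params$patch_size
  st <- params$stride
  patches <- vector("list", dims[1] * dims[2])
  info <- vector("list", dims[1] * dims[2])
  k <- 0L
  for (r in seq_len(dims[1])) {
    for (cc in seq_len(dims[2])) {
      k <- k + 1L
      y0 <- (r - 1L) * st
      x0 <- (cc - 1L) * st
      rows <- (y0 + 1L):(y0 + ps)
      cols <- (x0 + 1L):(x0 + ps)
      col_px <- sample$color_image[rows, cols, , drop = FALSE]
      p <- list(color = col_px, ri = sample$ri_image[rows, cols])
      if (!is.null(sample$nucleus_mask)) p$mask <- sample$nucleus_mask[rows, cols]
      patches[[k]] <- p
      info[[k]] <- data.frame(
        cluster_id = sample$cluster_id, grid_row = r, grid_col = cc,
        y0 = y0, x0 = x0, mean_color = mean(col_px),
        label = sample$label, stringsAsFactors = FALSE
      )
    }
  }
  structure(list(patches = patches, info = do.call(rbind, info), params = params),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches of %d px (stride %d)\n",
              nrow(x$info), x$params$patch_size, x$params$stride))
  invisible(x)
}

#' Pooled mean color count of a patch
#'
#' Arithmetic mean over all pixels and all three channels of the 8-bit color
#' patch; always in \[0, 255\].
#'
#' @param patch One element of a [tile_pair()] result (or any list with a
#'   `color` array).
#' @return A single number.
#' @export
mean_color_count <- function(patch) {
  mean(patch$color)
}

#' Apply the mean-color inclusion filter
#'
#' Retains exactly the patches whose pooled mean color count is greater than
#' or equal to the threshold (boundary inclusive). Retention is the only
#' criterion: qualifying patches containing only background are kept without
#' manual exclusion. Filtering preserves order and is idempotent.
#'
#' @param patch_set A [tile_pair()] result.
#' @param params A [tiling_params()].
#' @return A `patch_set` containing the retained patches; its `info` gains a
#'   `kept` column history via attribute `n_dropped`.
#' @export
filter_patches <- function(patch_set, params = patch_set$params) {
  keep <- patch_set$info$mean_color >= params$color_mean_threshold
  out <- patch_set
  out$patches <- patch_set$patches[keep]
  out$info <- patch_set$info[keep, , drop = FALSE]
  rownames(out$info) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}
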