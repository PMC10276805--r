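# On-disk interchange for generated datasets: color as 8-bit RGB PNG, RI as
# 32-bit float single-channel TIFF, nucleus mask as 16-bit integer TIFF,
# plus a CSV manifest (one row per cluster).

#' Export a generated dataset to disk
#'
#' Writes each cluster's color image (`<id>_color.png`), RI projection
#' (`<id>_ri.tif`, 32-bit float), ground-truth mask (`<id>_mask.tif`,
#' 16-bit) and a `clusters.csv` manifest with label, patient, file paths,
#' nucleus count and mean nucleus area.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame that was written.
#' @export
export_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cluster_dataset"))
  if (!requireNamespace("png", quietly = TRUE) ||
      !requireNamespace("tiff", quietly = TRUE)) {
    stop("export requires the png and tiff packages", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$samples, function(s) {
    base <- s$cluster_id
    png_path <- file.path(dir, paste0(base, "_color.png"))
    ri_path <- file.path(dir, paste0(base, "_ri.tif"))
    mask_path <- file.path(dir, paste0(base, "_mask.tif"))
    png::writePNG(s$color_image / 255, png_path)
    tiff::writeTIFF(s$ri_image / max(max(s$ri_image), 1e-9), ri_path,
                    bits.per.sample = 32)
    tiff::writeTIFF(s$nucleus_mask / 65535, mask_path, bits.per.sample = 16)
    data.frame(
      cluster_id = s$cluster_id, patient_id = s$patient_id, label = s$label,
      color_path = basename(png_path), ri_path = basename(ri_path),
      mask_path = basename(mask_path),
      n_nuclei = nrow(s$nucleus_table),
      mean_nucleus_area_um2 = mean(s$nucleus_table$area_um2),
      ri_scale = max(max(s$ri_image), 1e-9),
      stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "clusters.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one exported cluster back
#'
#' @param dir Directory written by [export_dataset()].
#' @param cluster_id Cluster to load.
#' @return A list with `color_image` (8-bit counts), `ri_image` (rescaled to
#'   the original units via the recorded `ri_scale`) and `nucleus_mask`.
#' @export
read_cluster_images <- function(dir, cluster_id) {
  manifest <- utils::read.csv(file.path(dir, "clusters.csv"), stringsAsFactors = FALSE)
  row <- manifest[manifest$cluster_id == cluster_id, ]
  if (nrow(row) != 1) stop("unknown cluster_id: ", cluster_id, call. = FALSE)
  col <- png::readPNG(file.path(dir, row$color_path))
  color <- round(col * 255)
  storage.mode(color) <- "integer"
  ri <- tiff::readTIFF(file.path(dir, row$ri_path)) * row$ri_scale
  mask <- round(tiff::readTIFF(file.path(dir, row$mask_path)) * 65535)
  storage.mode(mask) <- "integer"
  list(cluster_id = cluster_id, patient_id = row$patient_id, label = row$label,
       color_image = color, ri_image = ri, nucleus_mask = mask)
}
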