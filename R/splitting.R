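#' Grouped, stratified train/validation/test split
#'
#' Partitions clusters (the grouping unit: all patches of a cluster follow
#' their cluster) into train, validation and test sets. Within each class,
#' clusters are shuffled under the seed and allocated by largest-remainder
#' rounding so each partition's malignant fraction tracks the global
#' fraction as closely as integer counts allow. If a class has fewer
#' clusters than partitions, stratification degrades to a grouped-only split
#' with a warning. With `by_patient = TRUE` the grouping unit is the patient
#' (a stricter split than the cluster-level grouping used by default).
#'
#' @param clusters A data.frame with `cluster_id` and `label` (and
#'   `patient_id` when `by_patient = TRUE`).
#' @param ratios Three positive proportions summing to 1 for
#'   train/validation/test; the default follows a 988/261/286 cluster split.
#' @param seed Integer seed controlling the shuffle.
#' @param by_patient Group by patient instead of by cluster.
#' @return A data.frame (class `split_assignment`) with `cluster_id` and
#'   `partition` in `c("train", "validation", "test")`; partitions are
#'   pairwise disjoint and cover all clusters.
#' @export
grouped_stratified_split <- function(clusters, ratios = c(0.64, 0.17, 0.19),
                                     seed = 1, by_patient = FALSE) {
  stopifnot(is.data.frame(clusters), all(c("cluster_id", "label") %in% names(clusters)))
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three positive proportions summing to 1", call. = FALSE)
  }
  if (anyDuplicated(clusters$cluster_id)) {
    stop("duplicate cluster_id in input", call. = FALSE)
  }
  parts <- c("train", "validation", "test")

  unit_df <- if (by_patient) {
    stopifnot("patient_id" %in% names(clusters))
    u <- unique(clusters[, c("patient_id", "label")])
    data.frame(unit = u$patient_id, label = u$label, stringsAsFactors = FALSE)
  } else {
    data.frame(unit = clusters$cluster_id, label = clusters$label,
               stringsAsFactors = FALSE)
  }
  unit_df <- unit_df[order(unit_df$unit), ]  # deterministic base order

  classes <- split(unit_df$unit, unit_df$label)
  stratified <- all(vapply(classes, length, integer(1)) >= length(parts))
  if (!stratified) {
    warning("a class has fewer groups than partitions; falling back to a grouped-only split")
    classes <- list(all = unit_df$unit)
  }

  assignment <- with_seed(seed, {
    res <- lapply(classes, function(ids) {
      ids <- sample(ids)
      counts <- largest_remainder(length(ids), ratios)
      data.frame(unit = ids, partition = rep(parts, counts), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })

  out <- if (by_patient) {
    m <- assignment$partition[match(clusters$patient_id, assignment$unit)]
    data.frame(cluster_id = clusters$cluster_id, partition = m, stringsAsFactors = FALSE)
  } else {
    data.frame(cluster_id = assignment$unit, partition = assignment$partition,
               stringsAsFactors = FALSE)
  }
  out <- out[match(clusters$cluster_id, out$cluster_id), ]
  rownames(out) <- NULL

  # leakage/coverage assertions: every cluster in exactly one partition
  stopifnot(!anyNA(out$partition),
            identical(sort(out$cluster_id), sort(clusters$cluster_id)))
  attr(out, "ratios") <- ratios
  attr(out, "seed") <- seed
  class(out) <- c("split_assignment", "data.frame")
  out
}

# Integer allocation of n units to length(ratios) parts: floor plus
# largest-remainder top-up; remainder ties resolved in partition order.
largest_remainder <- function(n, ratios) {
  base <- floor(n * ratios)
  rem <- n * ratios - base
  extra <- n - sum(base)
  if (extra > 0) {
    ord <- order(-rem, seq_along(ratios))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Route patches to their cluster's partition
#'
#' Every patch inherits the partition of its cluster; no patch is duplicated
#' or dropped. A patch referencing an unknown cluster is a data-integrity
#' error.
#'
#' @param assignment A [grouped_stratified_split()] result.
#' @param patches A data.frame of patches with a `cluster_id` column (for
#'   example the `info` of a [tile_pair()] result).
#' @return A named list of three data.frames: `train`, `validation`, `test`.
#' @export
partition_patches <- function(assignment, patches) {
  stopifnot("cluster_id" %in% names(patches))
  idx <- match(patches$cluster_id, assignment$cluster_id)
  if (anyNA(idx)) {
    orphans <- unique(patches$cluster_id[is.na(idx)])
    stop("data-integrity error: patches reference unknown clusters: ",
         paste(head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  part <- assignment$partition[idx]
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(p) {
                  d <- patches[part == p, , drop = FALSE]
                  rownames(d) <- NULL
                  d
                })
  stopifnot(sum(vapply(out, nrow, integer(1))) == nrow(patches))
  out
}
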