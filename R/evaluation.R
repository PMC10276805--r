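#' Confusion matrix for binary malignancy calls
#'
#' Counts true negatives, false positives, false negatives and true
#' positives, with malignant as the positive class.
#'
#' @param truth,predicted Equal-length vectors with values `"benign"` /
#'   `"malignant"` (factors are accepted).
#' @return An object of class `confusion_matrix`: list with integer `tn`,
#'   `fp`, `fn`, `tp`.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("input error: truth and predicted must have equal length", call. = FALSE)
  }
  ok <- c("benign", "malignant")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("input error: labels must be 'benign' or 'malignant'", call. = FALSE)
  }
  as_confusion(
    tn = sum(truth == "benign" & predicted == "benign"),
    fp = sum(truth == "benign" & predicted == "malignant"),
    fn = sum(truth == "malignant" & predicted == "benign"),
    tp = sum(truth == "malignant" & predicted == "malignant")
  )
}

#' Build a confusion matrix from its four cell counts
#'
#' @param tn,fp,fn,tp Non-negative integer counts (positive class =
#'   malignant).
#' @return An object of class `confusion_matrix`.
#' @export
as_confusion <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("input error: confusion cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("benign", "malignant"),
                              predicted = c("benign", "malignant")))
  print(m)
  invisible(x)
}

#' Performance metrics of a confusion matrix
#'
#' Computes accuracy `(tn+tp)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, positive predictive value `tp/(tp+fp)` and negative
#' predictive value `tn/(tn+fn)`, plus each cell's fraction of the total.
#' A metric whose denominator is zero is reported as `NA` (not available),
#' never as 0 or 1. Values are exact; rounding (half-up to three decimals)
#' happens only at display time via `print()`.
#'
#' @param cm A [confusion()] / [as_confusion()] object.
#' @return An object of class `metric_set`: list with the five metrics,
#'   `cell_fractions` and the source counts.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total == 0) stop("empty-input error: confusion matrix has no observations", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    accuracy = (cm$tn + cm$tp) / total,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    cell_fractions = c(tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp) / total,
    counts = cm,
    total = total
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("n = %d | accuracy %s, sensitivity %s, specificity %s, PPV %s, NPV %s\n",
              x$total, format_metric(x$accuracy), format_metric(x$sensitivity),
              format_metric(x$specificity), format_metric(x$ppv), format_metric(x$npv)))
  invisible(x)
}

#' Exclude clusters with too few patches
#'
#' Result tables at the cluster level exclude clusters represented by fewer
#' than `min_patches` retained patches; clusters with exactly `min_patches`
#' are kept ("less than five" excluded). The filter applies to evaluation,
#' not to training.
#'
#' @param clusters A data.frame with an `n_patches` column.
#' @param min_patches Minimum retained patch count.
#' @return The eligible subset, same columns.
#' @export
filter_eligible <- function(clusters, min_patches = 5) {
  stopifnot("n_patches" %in% names(clusters))
  out <- clusters[clusters$n_patches >= min_patches, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate predicted labels against truth
#'
#' Joins predictions to truth by `id`, applies the minimum-patch eligibility
#' rule at cluster level, and reports one confusion matrix and metric set
#' per modality.
#'
#' @param predictions data.frame with `id`, `modality`, `label` (predicted).
#' @param truth data.frame with `id`, `label`, and (for cluster level)
#'   `n_patches`.
#' @param level `"patch"` or `"cluster"`.
#' @param min_patches Eligibility threshold used at cluster level.
#' @return A data.frame with one row per modality: `level`, `modality`,
#'   `n`, `tn`, `fp`, `fn`, `tp`, `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (unrounded).
#' @export
evaluate_run <- function(predictions, truth, level = c("cluster", "patch"),
                         min_patches = 5) {
  level <- match.arg(level)
  stopifnot(all(c("id", "modality", "label") %in% names(predictions)),
            all(c("id", "label") %in% names(truth)))
  if (anyDuplicated(truth$id)) stop("data-integrity error: duplicate ids in truth", call. = FALSE)
  if (!all(predictions$id %in% truth$id)) {
    stop("data-integrity error: predictions reference unknown ids", call. = FALSE)
  }
  if (level == "cluster") {
    stopifnot("n_patches" %in% names(truth))
    truth <- filter_eligible(truth, min_patches)
    predictions <- predictions[predictions$id %in% truth$id, , drop = FALSE]
  }
  idx <- match(predictions$id, truth$id)
  if (anyNA(idx)) {
    stop("data-integrity error: predictions reference unknown ids", call. = FALSE)
  }
  rows <- lapply(split(seq_len(nrow(predictions)), predictions$modality), function(i) {
    cm <- confusion(truth$label[idx[i]], predictions$label[i])
    ms <- classification_metrics(cm)
    data.frame(level = level, modality = predictions$modality[i][1],
               n = ms$total, tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp,
               accuracy = ms$accuracy, sensitivity = ms$sensitivity,
               specificity = ms$specificity, ppv = ms$ppv, npv = ms$npv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
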