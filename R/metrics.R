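# Confusion-based and threshold-sweep evaluation of probability maps
# against binary ground truth inside an evaluation mask.

# Coerce probability/mask inputs to a 2-d matrix (drops singleton dims).
as_grid <- function(x) {
  x <- drop(x)
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L)
  x
}

#' Confusion counts and derived rates inside an evaluation mask
#'
#' Binarizes the probability map at `>= threshold`, restricts all counting
#' to pixels where `eval_mask == 1`, and fills the full report: TP/FP/TN/FN
#' counts, sensitivity, specificity, accuracy, precision, Dice (identical
#' to per-pixel F1 for binary masks), IoU, and rank-based AUC. Rates with a
#' zero denominator are reported as `NaN` and listed in `undefined`.
#'
#' @param pred_prob Numeric matrix of probabilities in `[0, 1]`.
#' @param gt Binary matrix of the same shape.
#' @param eval_mask Binary matrix; pixels with 0 are excluded entirely.
#'   Defaults to all ones.
#' @param threshold Binarization threshold; ties resolve positive.
#' @return A list of class `metrics_report`.
#' @export
vessel_metrics <- function(pred_prob, gt, eval_mask = NULL, threshold = 0.5) {
  pred_prob <- as_grid(pred_prob); gt <- as_grid(gt)
  eval_mask <- if (is.null(eval_mask)) array(1, dim(gt)) else as_grid(eval_mask)
  if (!identical(dim(pred_prob), dim(gt)) || !identical(dim(gt), dim(eval_mask)))
    stop("pred_prob, gt, and eval_mask must share one shape")
  if (any(gt != 0 & gt != 1)) stop("gt must be binary")
  if (any(eval_mask != 0 & eval_mask != 1)) stop("eval_mask must be binary")
  inside <- eval_mask == 1
  p <- pred_prob[inside]
  y <- gt[inside]
  pb <- p >= threshold
  tp <- sum(pb & y == 1)
  fp <- sum(pb & y == 0)
  fn <- sum(!pb & y == 1)
  tn <- sum(!pb & y == 0)
  undefined <- character()
  rate <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NaN) }
    num / den
  }
  rep <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    n_eval = sum(inside),
    sensitivity = rate(tp, tp + fn, "sensitivity"),
    specificity = rate(tn, tn + fp, "specificity"),
    accuracy = rate(tp + tn, tp + fp + tn + fn, "accuracy"),
    precision = rate(tp, tp + fp, "precision"),
    dice = rate(2 * tp, 2 * tp + fp + fn, "dice"),
    iou = rate(tp, tp + fp + fn, "iou"),
    auc_roc = if (any(y == 1) && any(y == 0)) auc_roc(pred_prob, gt, eval_mask)
              else { undefined <- c(undefined, "auc_roc"); NaN },
    threshold = threshold)
  rep$undefined <- undefined
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (", x$n_eval, " evaluated pixels, threshold ",
      x$threshold, ")\n", sep = "")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  for (nm in c("sensitivity", "specificity", "accuracy", "precision",
               "dice", "iou", "auc_roc"))
    cat(sprintf("  %-12s %.4f\n", nm, x[[nm]]))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC over mask-interior pixels: the probability that a random
#' positive pixel scores higher than a random negative one, with midrank
#' handling of ties. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @inheritParams vessel_metrics
#' @return AUC in `[0, 1]`, or `NaN` (with a warning) if only one class is
#'   present inside the mask.
#' @export
auc_roc <- function(pred_prob, gt, eval_mask = NULL) {
  pred_prob <- as_grid(pred_prob); gt <- as_grid(gt)
  eval_mask <- if (is.null(eval_mask)) array(1, dim(gt)) else as_grid(eval_mask)
  inside <- eval_mask == 1
  p <- pred_prob[inside]
  y <- gt[inside]
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: only one class present inside the mask")
    return(NaN)
  }
  r <- rank(p)   # midranks for ties
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision-recall curve
#'
#' Precision and recall at `n_thresholds` evenly spaced thresholds in
#' `[0, 1]` plus the all-positive endpoint (threshold 0, recall 1). Recall
#' is non-increasing in the threshold. Precision at thresholds where
#' nothing is predicted positive is `NaN`.
#'
#' @inheritParams vessel_metrics
#' @param n_thresholds Number of evenly spaced thresholds.
#' @return `data.frame` with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(pred_prob, gt, eval_mask = NULL, n_thresholds = 50L) {
  pred_prob <- as_grid(pred_prob); gt <- as_grid(gt)
  eval_mask <- if (is.null(eval_mask)) array(1, dim(gt)) else as_grid(eval_mask)
  inside <- eval_mask == 1
  p <- pred_prob[inside]
  y <- gt[inside]
  if (!any(y == 1)) {
    warning("PR curve undefined: no positives inside the mask")
    return(data.frame(threshold = numeric(), recall = numeric(),
                      precision = numeric()))
  }
  ths <- unique(sort(c(0, seq(0, 1, length.out = n_thresholds)),
                     decreasing = TRUE))
  np <- sum(y == 1)
  out <- lapply(ths, function(th) {
    pb <- p >= th
    tp <- sum(pb & y == 1)
    data.frame(threshold = th, recall = tp / np,
               precision = if (sum(pb) == 0) NaN else tp / sum(pb))
  })
  do.call(rbind, out)
}

#' Evaluate a set of predictions
#'
#' Per-image [vessel_metrics()] plus a dataset-level aggregate (mean over
#' images of each defined rate).
#'
#' @param preds List of probability matrices.
#' @param gts List of binary ground-truth matrices.
#' @param fovs Optional list of FOV masks (`NULL` entries mean all-ones).
#' @param threshold Binarization threshold.
#' @return List with `per_image` (list of `metrics_report`) and `aggregate`
#'   (named means).
#' @export
evaluate_predictions <- function(preds, gts, fovs = NULL, threshold = 0.5) {
  stopifnot(length(preds) == length(gts))
  per <- lapply(seq_along(preds), function(i) {
    fov <- if (is.null(fovs)) NULL else fovs[[i]]
    vessel_metrics(preds[[i]], gts[[i]], fov, threshold)
  })
  fields <- c("sensitivity", "specificity", "accuracy", "precision",
              "dice", "iou", "auc_roc")
  agg <- vapply(fields, function(f)
    mean(vapply(per, function(r) r[[f]], numeric(1)), na.rm = TRUE),
    numeric(1))
  list(per_image = per, aggregate = as.list(agg))
}
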