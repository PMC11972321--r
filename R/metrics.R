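#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("inputs must be binary 0/1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " has zero denominator; defined as 0")
    return(0)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall (= TPR)
#' `TP/(TP+FN)`, FPR `FP/(TN+FP)`, and the F1 score. The default F1 is the
#' standard harmonic mean `2PR/(P+R)`; `f1_variant = "printed_half"`
#' computes `0.5 * PR/(P+R)` instead, a non-standard halved variant exposed
#' for comparison studies. Degenerate denominators yield 0 with a warning.
#'
#' @param counts A `confusion_counts`.
#' @param f1_variant `"standard"` (default) or `"printed_half"`.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `tpr`,
#'   `fpr`.
#' @export
classification_metrics <- function(counts, f1_variant = c("standard",
                                                          "printed_half")) {
  f1_variant <- match.arg(f1_variant)
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  acc <- safe_ratio(counts$TP + counts$TN, n, "accuracy")
  prec <- safe_ratio(counts$TP, counts$TP + counts$FP, "precision")
  rec <- safe_ratio(counts$TP, counts$TP + counts$FN, "recall")
  fpr <- safe_ratio(counts$FP, counts$TN + counts$FP, "FPR")
  f1 <- if (prec + rec == 0) {
    warning("F1 has zero denominator; defined as 0")
    0
  } else {
    base <- prec * rec / (prec + rec)
    if (f1_variant == "standard") 2 * base else 0.5 * base
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       tpr = rec, fpr = fpr)
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique scores (ties grouped), anchoring the
#' curve at (0, 0) and (1, 1); points are ordered by increasing FPR.
#'
#' @param y_true Binary 0/1 labels (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return List with `fpr` and `tpr` vectors.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L) stop("both classes must be present")
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == 0) / nn,
                numeric(1))
  list(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Area under an ROC curve (trapezoid rule)
#'
#' @param fpr,tpr Coordinates as returned by [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Dice overlap of two masks for one class
#'
#' `2|A n B| / (|A| + |B|)`, defined as 1 when both masks are empty for the
#' class.
#'
#' @param pred_mask,true_mask Equal-shape integer masks.
#' @param class_id Label whose overlap is measured.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(pred_mask, true_mask, class_id = 1L) {
  if (!all(dim(pred_mask) == dim(true_mask))) stop("shape mismatch")
  a <- pred_mask == class_id
  b <- true_mask == class_id
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Intersection-over-union of two masks for one class
#'
#' `|A n B| / (|A u B)|`, defined as 1 when both are empty; algebraically
#' `dice / (2 - dice)`.
#'
#' @inheritParams dice_score
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(pred_mask, true_mask, class_id = 1L) {
  if (!all(dim(pred_mask) == dim(true_mask))) stop("shape mismatch")
  a <- pred_mask == class_id
  b <- true_mask == class_id
  uni <- sum(a | b)
  if (uni == 0) return(1.0)
  sum(a & b) / uni
}

#' Full metric report for binary predictions
#'
#' @param y_true Binary labels.
#' @param scores Predicted probabilities/scores.
#' @param threshold Classification threshold (default 0.5).
#' @param f1_variant See [classification_metrics()].
#' @return A `metric_report` list: confusion counts, all rate metrics, and
#'   `auc`.
#' @export
metric_report <- function(y_true, scores, threshold = 0.5,
                          f1_variant = "standard") {
  cm <- confusion(y_true, as.integer(scores >= threshold))
  m <- classification_metrics(cm, f1_variant)
  roc <- roc_curve(y_true, scores)
  structure(c(list(confusion = cm), m, list(auc = auc(roc$fpr, roc$tpr))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | precision %.4f | recall %.4f | f1 %.4f | auc %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}
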