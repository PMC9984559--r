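## Confusion-based metrics and probabilistic ROC/AUC.

#' Confusion counts for deleterious/unknown calls
#'
#' Mapping: predicted deleterious on a pathogenic truth is TP; predicted
#' unknown on a benign truth is TN; deleterious on benign is FP; unknown on
#' pathogenic is FN.
#'
#' @param preds Character vector in `{"deleterious", "unknown"}`.
#' @param truth Character vector in `{"benign", "pathogenic"}`, same length.
#' @return An object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(preds, truth) {
  if (length(preds) != length(truth)) stop_dlrpmds("length mismatch")
  if (!all(truth %in% c("benign", "pathogenic")))
    stop_dlrpmds("truth labels must be benign/pathogenic")
  if (!all(preds %in% c("deleterious", "unknown")))
    stop_dlrpmds("predictions must be deleterious/unknown")
  structure(list(
    tp = sum(preds == "deleterious" & truth == "pathogenic"),
    fp = sum(preds == "deleterious" & truth == "benign"),
    tn = sum(preds == "unknown" & truth == "benign"),
    fn = sum(preds == "unknown" & truth == "pathogenic")),
    class = "confusion_counts")
}

#' F-beta score with beta = 2
#'
#' `(1 + b^2) * precision * recall / (b^2 * precision + recall)` with
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `b = 2` (recall-weighted).
#' Degenerate denominators yield 0 with a warning.
#'
#' @param counts A [confusion()] result (or list with tp/fp/fn).
#' @param beta Weight on recall, default 2.
#' @return Numeric in `[0, 1]`.
#' @export
f2_score <- function(counts, beta = 2) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp == 0 || tp + fn == 0) {
    warning("degenerate confusion counts; F-score defined as 0")
    return(0)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param counts A [confusion()] result.
#' @return Numeric in `[0, 1]`.
#' @export
accuracy_score <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop_dlrpmds("empty confusion counts")
  (counts$tp + counts$tn) / total
}

#' Balanced accuracy
#'
#' Mean of the true-positive and true-negative rates, `(TPR + TNR) / 2`.
#'
#' @param tpr,tnr Rates in `[0, 1]` (sensitivity and specificity).
#' @return Numeric in `[0, 1]`.
#' @export
balanced_accuracy <- function(tpr, tnr) {
  if (any(tpr < 0 | tpr > 1) || any(tnr < 0 | tnr > 1))
    stop_dlrpmds("rates must lie in [0, 1]")
  (tpr + tnr) / 2
}

# Balanced accuracy straight from confusion counts.
balanced_accuracy_counts <- function(counts) {
  tpr <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  tnr <- if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp) else NA_real_
  balanced_accuracy(tpr, tnr)
}

#' ROC curve and AUC for probabilistic predictions
#'
#' Threshold sweep over the unique predicted probabilities (plus sentinels so
#' the curve spans (0,0)-(1,1)); AUC by the trapezoid rule, which equals the
#' Mann-Whitney pairwise concordance with ties counted one half.
#'
#' @param p_deleterious Predicted probability of the deleterious class.
#' @param truth Character vector in `{"benign", "pathogenic"}`; both classes
#'   must be present.
#' @return List with `points` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc_probabilistic <- function(p_deleterious, truth) {
  if (length(p_deleterious) != length(truth)) stop_dlrpmds("length mismatch")
  pos <- truth == "pathogenic"
  if (!any(pos) || all(pos))
    stop_dlrpmds("both classes must be present to compute a ROC curve")
  ord <- order(p_deleterious, decreasing = TRUE)
  p_s <- p_deleterious[ord]
  tp_cum <- cumsum(pos[ord])
  fp_cum <- cumsum(!pos[ord])
  last <- which(!duplicated(p_s, fromLast = TRUE))  # last row of each threshold
  tpr <- c(0, tp_cum[last] / sum(pos))
  fpr <- c(0, fp_cum[last] / sum(!pos))
  thr <- c(Inf, p_s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}
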