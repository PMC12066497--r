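# Link-prediction metric suite: threshold-based confusion metrics, rank-based
# ROC AUC (Mann-Whitney with mid-rank tie handling) and step-wise PR AUC.

check_labels <- function(labels) {
  labels <- as.numeric(labels)
  if (length(labels) == 0L) stop_input("at least one sample is required")
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop_input("labels must be 0/1")
  }
  labels
}

#' Confusion-matrix metrics at a threshold
#'
#' Accuracy, sensitivity (recall), specificity, precision and Matthews
#' correlation coefficient of `scores >= threshold`.  Any metric whose
#' denominator is zero is returned as 0 and named in the `"degenerate"`
#' attribute (with a warning), so tiny ablation folds never crash.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores.
#' @param threshold Decision threshold (predict positive at
#'   `score >= threshold`).
#' @return Named numeric vector `acc`, `sen`, `spec`, `pre`, `mcc` with a
#'   `"degenerate"` attribute listing zero-denominator metrics.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- check_labels(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else {
      num / den
    }
  }
  out <- c(
    acc = (tp + tn) / length(labels),
    sen = safe(tp, tp + fn, "sen"),
    spec = safe(tn, tn + fp, "spec"),
    pre = safe(tp, tp + fp, "pre"),
    mcc = safe(tp * tn - fp * fn,
               sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn),
               "mcc")
  )
  if (length(degenerate)) {
    warning("zero-denominator metric(s) returned as 0: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC AUC by rank statistics
#'
#' The Mann-Whitney probability `P(score_pos > score_neg) +
#' 0.5 P(tie)`, computed from mid-ranks.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- check_labels(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop_input("ROC AUC is undefined with a single class")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall step curve
#'
#' Scores are swept from high to low over the distinct thresholds; the area
#' is the step-wise sum of `precision(t) * delta recall(t)` with no linear
#' interpolation of precision.
#'
#' @param labels 0/1 vector with at least one positive.
#' @param scores Numeric scores.
#' @return AUPR in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  labels <- check_labels(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop_input("PR AUC is undefined with no positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]
  fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Validation threshold by Youden's J
#'
#' Returns the candidate threshold (among the distinct scores) maximizing
#' `sensitivity + specificity - 1`; ties resolve to the highest threshold.
#'
#' @param labels 0/1 vector with both classes.
#' @param scores Numeric scores.
#' @return The selected threshold.
#' @export
youden_threshold <- function(labels, scores) {
  labels <- check_labels(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop_input("threshold selection needs both classes")
  }
  cand <- sort(unique(scores), decreasing = TRUE)
  j <- vapply(cand, function(t) {
    sum(scores >= t & labels == 1) / n_pos -
      sum(scores >= t & labels == 0) / n_neg
  }, numeric(1))
  cand[which.max(j)]
}
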