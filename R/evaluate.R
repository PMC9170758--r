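# Evaluation statistics: ROC/AUC, confusion-based metrics, pooled CV
# evaluation, and cross-dataset application of a trained model.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) implementation: the fraction of
#' (positive, negative) score pairs ordered correctly, with ties credited
#' one half — equivalent to the trapezoidal ROC area.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1, or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires at least one positive and one negative label")
  }
  r <- rank(scores)   # average ranks give the half-credit tie convention
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based confusion metrics
#'
#' Calls a sample positive when `score > threshold` (strict, matching the
#' tPPS indicator convention) and reports precision, recall, F1, and the
#' Matthews correlation coefficient. Any metric with a zero denominator is
#' reported as 0 and named in the `degenerate` field rather than propagating
#' NaN.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param threshold Score cutoff (default 0.5).
#' @return Object of class `eval_metrics`: `auc` (NA here; see
#'   [evaluate_cv()]), `precision`, `recall`, `f1`, `mcc`, `threshold`,
#'   `counts` (TP/FP/FN/TN), `degenerate`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  stopifnot(length(scores) == length(labels))
  pred <- scores > threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  degenerate <- character()

  div <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- div(2 * precision * recall, precision + recall, "f1")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  structure(list(auc = NA_real_, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc, threshold = threshold,
                 counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 degenerate = degenerate),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4f  precision %.4f  recall %.4f  F1 %.4f  MCC %.4f (threshold %g)\n",
              x$auc, x$precision, x$recall, x$f1, x$mcc, x$threshold))
  cat("counts:", paste(names(x$counts), x$counts, collapse = "  "), "\n")
  if (length(x$degenerate)) {
    cat("degenerate (zero-denominator) metrics:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate pooled out-of-fold cross-validation predictions
#'
#' Metrics are computed once on the pooled out-of-fold score vector — every
#' sample predicted exactly once by the model that never saw it — not
#' averaged per fold.
#'
#' @param cv A `cv_result` from [cross_validate()] or [nested_cv()].
#' @param threshold Cutoff for the confusion-based metrics.
#' @return An `eval_metrics` object with `auc` filled in.
#' @export
evaluate_cv <- function(cv, threshold = 0.5) {
  stopifnot(inherits(cv, "cv_result"))
  if (anyNA(cv$scores)) {
    stop("incomplete pooling: some samples have no out-of-fold prediction")
  }
  m <- confusion_metrics(cv$scores, cv$labels, threshold)
  m$auc <- roc_auc(cv$scores, cv$labels)
  m
}

#' Apply a trained model to an independent sample set
#'
#' Predicts and evaluates without retraining — the protocol used for
#' cross-species transfer testing (train on one species, test on the other)
#' and for imbalanced held-out sets.
#'
#' @param model A trained `psicnn_model`.
#' @param foreign_samples data.frame with `sequence` and `label` columns; the
#'   windows must match the model's input length.
#' @param threshold Cutoff for the confusion-based metrics.
#' @return An `eval_metrics` object with `auc` filled in, plus the raw
#'   `scores` as an attribute.
#' @export
cross_apply <- function(model, foreign_samples, threshold = 0.5) {
  stopifnot(inherits(model, "psicnn_model"))
  if (!all(nchar(foreign_samples$sequence) == model$config$input_len)) {
    stop("foreign samples do not match the model input length ",
         model$config$input_len)
  }
  scores <- predict(model, foreign_samples$sequence)
  m <- confusion_metrics(scores, foreign_samples$label, threshold)
  m$auc <- roc_auc(scores, foreign_samples$label)
  attr(m, "scores") <- scores
  m
}

#' Write an eval_metrics object as a JSON report
#' @param metrics An `eval_metrics` object.
#' @param path Output JSON path.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' ROC curve points
#'
#' Returns the (FPR, TPR) step-curve points for a score vector, one row per
#' distinct threshold.
#' @param scores,labels As in [roc_auc()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  n1 <- sum(l); n0 <- length(l) - n1
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(diff(s) != 0, TRUE)   # last point at each distinct threshold
  data.frame(threshold = s[keep], fpr = fp[keep] / n0, tpr = tp[keep] / n1)
}
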