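#' Threshold a fused score vector into binary predictions
#'
#' The decision rule is inclusive: predict the disease class (1) when
#' `score >= tau`. Consequently `tau = 0` predicts every sample positive.
#'
#' @param fused a [fused_scores()] object or numeric score vector.
#' @param tau decision threshold in `[0, 1]`.
#' @return integer vector of 0/1 predictions.
#' @export
apply_threshold <- function(fused, tau) {
  if (!is_scalar_number(tau) || tau < 0 || tau > 1) {
    drf_stop("`tau` must be a probability in [0, 1]")
  }
  as.integer(as_scores(fused) >= tau)
}

#' Confusion matrix for a binary screen
#'
#' Counts follow the row convention `[[TN, FP], [FN, TP]]`: rows are the true
#' class (No_DR, DR), columns the predicted class.
#'
#' @param labels 0/1 ground-truth vector (0 = No_DR, 1 = DR).
#' @param preds 0/1 prediction vector of the same length.
#' @return an object of class `confusion_matrix` with fields `tn`, `fp`,
#'   `fn`, `tp`.
#' @export
confusion <- function(labels, preds) {
  labels <- as.integer(labels)
  preds <- as.integer(preds)
  if (length(labels) != length(preds)) {
    drf_stop("`labels` and `preds` must have equal length")
  }
  if (length(labels) < 1L) drf_stop("empty label vector")
  if (!all(labels %in% c(0L, 1L)) || !all(preds %in% c(0L, 1L))) {
    drf_stop("labels and predictions must be 0/1")
  }
  confusion_matrix(
    tn = sum(labels == 0L & preds == 0L),
    fp = sum(labels == 0L & preds == 1L),
    fn = sum(labels == 1L & preds == 0L),
    tp = sum(labels == 1L & preds == 1L)
  )
}

#' Construct a confusion matrix from counts
#' @param tn,fp,fn,tp nonnegative integer counts (total must be >= 1).
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    drf_stop("confusion counts must be nonnegative integers")
  }
  if (sum(counts) < 1) drf_stop("confusion matrix must contain at least one sample")
  structure(lapply(as.list(counts), as.integer), class = "confusion_matrix")
}

#' @export
as.matrix.confusion_matrix <- function(x, ...) {
  matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
         dimnames = list(true = c("No_DR", "DR"), pred = c("No_DR", "DR")))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Screening metrics from a confusion matrix
#'
#' All metrics are percentages kept at full precision; round only for display.
#' Zero-denominator conventions: precision is 0 when no positives are
#' predicted, recall is 0 when there are no true positives among the
#' positives, and F1 is 0 when precision + recall is 0.
#'
#' @param cm a [confusion_matrix()].
#' @param auc optional ROC-AUC percentage to carry alongside (see
#'   [roc_auc()]).
#' @return an object of class `metric_report`: list with `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1`, `balanced_accuracy`, `auc`
#'   (possibly `NA`), all on the 0-100 scale.
#' @examples
#' metrics_from_confusion(confusion_matrix(354, 7, 3, 369))
#' @export
metrics_from_confusion <- function(cm, auc = NA_real_) {
  if (!inherits(cm, "confusion_matrix")) drf_stop("expected a `confusion_matrix`")
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  accuracy <- (cm$tp + cm$tn) / total
  recall <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
  specificity <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else 0
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(accuracy = 100 * accuracy,
         precision = 100 * precision,
         recall = 100 * recall,
         specificity = 100 * specificity,
         f1 = 100 * f1,
         balanced_accuracy = 100 * (recall + specificity) / 2,
         auc = auc),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  vals <- unlist(x)
  for (nm in names(vals)) {
    if (is.na(vals[[nm]])) next
    cat(sprintf("%-18s %6.2f%%\n", nm, vals[[nm]]))
  }
  invisible(x)
}

#' ROC area under the curve (percentage)
#'
#' Computed as the Mann-Whitney U statistic normalized by the number of
#' positive-negative pairs, with midrank handling of ties; this equals the
#' trapezoidal area under the empirical ROC curve over all score thresholds.
#'
#' @param labels 0/1 ground-truth vector; both classes must be present.
#' @param scores a [fused_scores()] object or numeric score vector.
#' @return AUC as a percentage in `[0, 100]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  s <- as_scores(scores)
  if (length(labels) != length(s)) drf_stop("labels and scores length mismatch")
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    drf_stop("ROC-AUC needs both classes present in `labels`")
  }
  r <- rank(s, ties.method = "average")
  u <- sum(r[labels == 1L]) - npos * (npos + 1) / 2
  100 * u / (npos * nneg)
}

#' Sweep the decision threshold for the best operating point
#'
#' Evaluates the chosen objective on the grid `tau = 0, step, 2*step, ..., 1`
#' and returns the smallest grid point attaining the maximum. Smallest-wins
#' tie-breaking favors recall, the natural priority when missed disease cases
#' are the costly error. The threshold is, by default, tuned on the same
#' scores it is later applied to; for new studies prefer tuning on a held-out
#' split (see [stratified_split()]).
#'
#' @param labels 0/1 ground-truth vector; both classes must be present.
#' @param scores a [fused_scores()] object or numeric score vector.
#' @param objective metric to maximize: `"f1"`, `"balanced_accuracy"` or
#'   `"accuracy"`.
#' @param step grid spacing in `(0, 1]`, default 0.01.
#' @return an object of class `threshold_result`: list with `tau_star`,
#'   `objective`, `best_value` (percentage), and `curve` (data.frame of
#'   `tau`, `value`).
#' @export
optimize_threshold <- function(labels, scores,
                               objective = c("f1", "balanced_accuracy", "accuracy"),
                               step = 0.01) {
  objective <- match.arg(objective)
  labels <- as.integer(labels)
  s <- as_scores(scores)
  if (length(labels) != length(s)) drf_stop("labels and scores length mismatch")
  if (!is_scalar_number(step) || step <= 0 || step > 1) {
    drf_stop("`step` must lie in (0, 1]")
  }
  if (length(unique(labels)) < 2L) {
    drf_stop("threshold optimization needs both classes present in `labels`")
  }
  taus <- (0:floor(1 / step + 1e-9)) * step
  taus[taus > 1] <- 1
  vals <- vapply(taus, function(tau) {
    m <- metrics_from_confusion(confusion(labels, as.integer(s >= tau)))
    m[[objective]]
  }, numeric(1))
  best <- which.max(vals)  # first = smallest tau attaining the grid maximum
  structure(
    list(tau_star = taus[best], objective = objective,
         best_value = vals[best],
         curve = data.frame(tau = taus, value = vals)),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> tau* = %.4g maximizing %s = %.2f%% (grid of %d)\n",
              x$tau_star, x$objective, x$best_value, nrow(x$curve)))
  invisible(x)
}

#' Write a threshold sweep curve as TSV (`tau<TAB>objective`)
#' @param result a `threshold_result` from [optimize_threshold()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_threshold_curve <- function(result, path) {
  if (!inherits(result, "threshold_result")) drf_stop("expected a `threshold_result`")
  df <- data.frame(tau = fmt_num(result$curve$tau, 4),
                   objective = fmt_num(result$curve$value, 6))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate fused scores against labels at a threshold
#'
#' Convenience wrapper: threshold, confusion matrix, metrics and AUC in one
#' call.
#'
#' @inheritParams optimize_threshold
#' @param tau decision threshold.
#' @return list with `confusion` ([confusion_matrix()]) and `metrics`
#'   (`metric_report`, AUC included).
#' @export
evaluate_scores <- function(labels, scores, tau = 0.5) {
  preds <- apply_threshold(scores, tau)
  cm <- confusion(labels, preds)
  auc <- tryCatch(roc_auc(labels, scores), drf_error = function(e) NA_real_)
  list(confusion = cm, metrics = metrics_from_confusion(cm, auc = auc))
}
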