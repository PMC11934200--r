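.check_binary <- function(x, what) {
  if (!all(x %in% c(0L, 1L))) stop(what, " must contain only 0/1 values")
}

#' Confusion-matrix counts
#'
#' @param y_true,y_pred equal-length binary (0/1) vectors.
#' @return object of class `confusion_counts` with fields TP, FP, TN, FN.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  .check_binary(y_true, "y_true"); .check_binary(y_pred, "y_pred")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$TP, "FP", x$FP, "TN", x$TN, "FN", x$FN, "\n")
  invisible(x)
}

#' @rdname scalar_metrics
#' @export
accuracy <- function(cm) (cm$TP + cm$TN) / (cm$TP + cm$FP + cm$TN + cm$FN)

#' Scalar classification metrics
#'
#' Precision, recall, accuracy, F1, Matthews correlation coefficient and
#' Cohen's kappa from confusion counts. Degenerate denominators return 0
#' with a warning (so reports stay total under class collapse).
#'
#' @param cm a `confusion_counts` object.
#' @name scalar_metrics
#' @export
precision <- function(cm) {
  if (cm$TP + cm$FP == 0) { warning("no positive predictions; precision = 0"); return(0) }
  cm$TP / (cm$TP + cm$FP)
}

#' @rdname scalar_metrics
#' @export
recall <- function(cm) {
  if (cm$TP + cm$FN == 0) { warning("no positive truth; recall = 0"); return(0) }
  cm$TP / (cm$TP + cm$FN)
}

#' F1 score from a precision/recall pair
#'
#' The harmonic mean 2pr/(p+r); 0 when both are 0.
#'
#' @param precision,recall values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); 0 by convention
#' when any denominator factor vanishes. MCC stays informative under class
#' imbalance because it weighs all four confusion cells.
#'
#' @param cm a `confusion_counts`.
#' @return value in \[-1, 1\].
#' @export
mcc <- function(cm) {
  f <- c(cm$TP + cm$FP, cm$TP + cm$FN, cm$TN + cm$FP, cm$TN + cm$FN)
  if (any(f == 0)) { warning("degenerate confusion matrix; MCC = 0"); return(0) }
  (cm$TP * cm$TN - cm$FP * cm$FN) / prod(sqrt(f))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e), with expected
#' agreement p_e from the confusion-matrix marginals; 0 when p_e = 1.
#'
#' @param cm a `confusion_counts`.
#' @return value in \[-1, 1\].
#' @export
kappa_score <- function(cm) {
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  stopifnot(n > 0)
  po <- (cm$TP + cm$TN) / n
  pe <- ((cm$TP + cm$FP) * (cm$TP + cm$FN) + (cm$TN + cm$FN) * (cm$TN + cm$FP)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outscores a random negative, ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param y_true binary labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) stop("length mismatch")
  .check_binary(y_true, "y_true")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) stop("roc_auc needs both classes present")
  r <- rank(scores)
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metrics report for one task
#'
#' Computes the evaluation table row (precision, recall, F1, accuracy, MCC,
#' kappa, ROC-AUC) from predicted class-1 probabilities.
#'
#' @param y_true binary labels.
#' @param prob class-1 probabilities.
#' @param task task name carried into the row.
#' @param threshold probability cutoff for the positive class (default 0.5).
#' @return one-row data.frame of class `metrics_report`.
#' @export
metrics_report <- function(y_true, prob, task = "task", threshold = 0.5) {
  y_pred <- as.integer(prob >= threshold)
  cc <- confusion(y_true, y_pred)
  p <- suppressWarnings(precision(cc))
  r <- suppressWarnings(recall(cc))
  out <- data.frame(
    task = task,
    precision = p, recall = r, f1 = f1_score(p, r),
    accuracy = accuracy(cc),
    mcc = suppressWarnings(mcc(cc)),
    kappa = kappa_score(cc),
    roc_auc = roc_auc(prob, y_true),
    stringsAsFactors = FALSE
  )
  class(out) <- c("metrics_report", class(out))
  out
}
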