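#' Confusion matrix for the two-class screen
#'
#' Tallies TP/FN/FP/TN with leukemia as the positive class.
#'
#' @param y_true,y_pred vectors of `"leukemia"` / `"normal"`, equal length.
#' @return list of class `confusion_2x2` with integer fields `tp, fn, fp, tn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("confusion: length mismatch")
  if (length(y_true) < 1) stop("confusion: empty input")
  pos <- y_true == "leukemia"
  ppos <- y_pred == "leukemia"
  structure(list(tp = sum(pos & ppos), fn = sum(pos & !ppos),
                 fp = sum(!pos & ppos), tn = sum(!pos & !ppos)),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(true = c("leukemia", "normal"),
                              predicted = c("leukemia", "normal")))
  print(m)
  invisible(x)
}

#' Accuracy, precision, sensitivity and specificity
#'
#' The four screening metrics as percentages:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, each times 100. A zero
#' denominator yields `NaN` with a warning — never a silent zero.
#'
#' @param cm a [confusion()] result.
#' @return named numeric vector of percentages.
#' @export
classification_metrics <- function(cm) {
  tot <- cm$tp + cm$fn + cm$fp + cm$tn
  if (tot == 0) stop("classification_metrics: empty confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NaN)
    }
    100 * num / den
  }
  c(accuracy = 100 * (cm$tp + cm$tn) / tot,
    precision = ratio(cm$tp, cm$tp + cm$fp, "precision"),
    sensitivity = ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = ratio(cm$tn, cm$tn + cm$fp, "specificity"))
}

#' ROC curve and rank-based AUC
#'
#' AUC is the Mann-Whitney statistic — the probability that a random
#' positive outscores a random negative, ties counted one half — reported as
#' a percentage. (A ratio of sensitivity to specificity is sometimes quoted
#' as an AUC shorthand, but it is not a bounded area and is not used here.)
#' The curve lists TPR versus FPR over all score thresholds, from (0,0) to
#' (1,1).
#'
#' @param scores numeric vector (higher = more leukemia-like).
#' @param y_true `"leukemia"` / `"normal"` per score.
#' @return list of class `roc_result` with `auc` (percentage) and `curve`
#'   (data.frame `fpr, tpr`).
#' @export
roc_auc <- function(scores, y_true) {
  pos <- y_true == "leukemia"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores)  # midranks handle ties at 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores[pos] >= t) / n1, 0)
  fpr <- vapply(th, function(t) sum(scores[!pos] >= t) / n0, 0)
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(auc = 100 * auc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.2f%% (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' Error histogram
#'
#' Histogram of the residuals `actual - predicted` in `bins` equal-width
#' bins spanning the residual range (the classic 20-bin training diagnostic).
#' Counts sum to the sample count.
#'
#' @param actual,predicted numeric vectors of equal length.
#' @param bins number of bins (default 20).
#' @return list with `breaks` (length `bins + 1`) and `counts`.
#' @export
error_histogram <- function(actual, predicted, bins = 20L) {
  if (length(actual) == 0) stop("error_histogram: empty input")
  if (length(actual) != length(predicted)) stop("error_histogram: length mismatch")
  e <- actual - predicted
  lo <- min(e); hi <- max(e)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = bins + 1)
  idx <- pmin(pmax(floor((e - lo) / (hi - lo) * bins), 0), bins - 1)
  list(breaks = breaks, counts = tabulate(idx + 1L, nbins = bins))
}

#' Regression R between actual and predicted outputs
#'
#' Pearson correlation; values near 1 indicate the network output tracks the
#' targets. Zero variance in either vector yields `NA` with a warning.
#'
#' @param actual,predicted numeric vectors, length >= 2.
#' @return scalar in \[-1, 1\] or `NA`.
#' @export
regression_r <- function(actual, predicted) {
  if (length(actual) < 2) stop("regression_r: need at least 2 points")
  if (sd(actual) == 0 || sd(predicted) == 0) {
    warning("regression_r undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(actual, predicted)
}

#' Build a full evaluation report
#'
#' Bundles the confusion matrix, the four percentage metrics, ROC/AUC, the
#' 20-bin error histogram of the positive-class score against the 0/1
#' target, and the regression R.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param scores positive-class scores (for ROC, histogram, regression).
#' @return list of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred, scores) {
  cm <- confusion(y_true, y_pred)
  target <- as.numeric(y_true == "leukemia")
  roc <- roc_auc(scores, y_true)
  structure(list(confusion = cm,
                 metrics = suppressWarnings(classification_metrics(cm)),
                 auc = roc$auc, roc_curve = roc$curve,
                 error_histogram = error_histogram(target, scores),
                 regression_r = suppressWarnings(regression_r(target, scores)),
                 n = length(y_true)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (n = %d)\n", x$n))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              m["accuracy"], m["precision"], m["sensitivity"], m["specificity"]))
  cat(sprintf("AUC %.2f%%  regression R %.4f\n", x$auc, x$regression_r))
  invisible(x)
}
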