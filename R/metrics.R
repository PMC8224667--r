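#' One-vs-rest confusion counts
#'
#' Tallies TP, FP, TN, FN treating `positive` as the positive class and
#' everything else as negative.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the positive class label.
#' @return a list of class `confusion_counts` with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' The five classification metrics used throughout the package:
#' \deqn{Sensitivity = TP/(TP+FN)}
#' \deqn{Accuracy = (TP+TN)/(TP+FP+FN+TN)}
#' \deqn{Precision = TP/(TP+FP)}
#' \deqn{DICE = 2TP/(2TP+FP+FN)}
#' \deqn{AUC = 1 - (FP/(FP+TN) + FN/(FN+TP))/2}
#' The AUC here is the closed-form balanced accuracy
#' `(sensitivity + specificity)/2`, not a rank statistic. Metrics with a
#' zero denominator are returned as `NA` and listed in the `undefined`
#' attribute rather than silently coerced to 0 or 1.
#'
#' @param counts a [confusion_counts()] result.
#' @return a named numeric vector `(sensitivity, accuracy, precision,
#'   dice, auc)` with attribute `undefined` naming any flagged metrics.
#' @export
metric_suite <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (tp + fp + tn + fn == 0)
    stop("all confusion counts are zero", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(tp, tp + fn)
  acc <- (tp + tn) / (tp + fp + fn + tn)
  prec <- safe(tp, tp + fp)
  dice <- safe(2 * tp, 2 * tp + fp + fn)
  fpr <- safe(fp, fp + tn)
  fnr <- safe(fn, fn + tp)
  auc <- if (is.na(fpr) || is.na(fnr)) NA_real_ else 1 - (fpr + fnr) / 2
  out <- c(sensitivity = sens, accuracy = acc, precision = prec,
           dice = dice, auc = auc)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Mean squared error between outputs and targets
#'
#' @param outputs numeric matrix (or vector) of network outputs.
#' @param targets one-hot target matrix of the same shape.
#' @return the mean of the squared residuals over all samples and units.
#' @export
mse <- function(outputs, targets) {
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (!all(dim(outputs) == dim(targets)))
    stop("outputs and targets must have identical shape", call. = FALSE)
  mean((outputs - targets)^2)
}

#' Per-class classification report
#'
#' One-vs-rest [metric_suite()] for every class, the standard multiclass
#' summary layout (metric x class).
#'
#' @param y_true,y_pred label vectors.
#' @param classes class labels to report (default: observed in `y_true`).
#' @return a list of class `classification_report` with `metrics` (a
#'   matrix, classes in rows), `counts` (per-class confusion counts) and
#'   the overall `accuracy`.
#' @export
classification_report <- function(y_true, y_pred,
                                  classes = sort(unique(as.character(y_true)))) {
  counts <- lapply(classes, function(cl) confusion_counts(y_true, y_pred, cl))
  names(counts) <- classes
  metrics <- t(vapply(counts, metric_suite, numeric(5L)))
  structure(list(metrics = metrics, counts = counts,
                 accuracy = mean(as.character(y_pred) == as.character(y_true))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.3f\n", x$accuracy))
  print(round(x$metrics, 4))
  invisible(x)
}
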