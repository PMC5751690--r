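#' One-vs-rest confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_counts")
}

#' Per-class confusion counts from label vectors
#'
#' Computes one-vs-rest TP/TN/FP/FN for each class present in `classes`.
#'
#' @param pred,obs label vectors of equal length.
#' @param classes class universe (defaults to values seen in `obs`/`pred`).
#' @return Named list of `confusion_counts`, one per class.
#' @export
confusion_by_class <- function(pred, obs, classes = sort(unique(c(obs, pred)))) {
  stopifnot(length(pred) == length(obs), length(obs) > 0)
  out <- lapply(classes, function(k) {
    confusion_counts(TP = sum(pred == k & obs == k),
                     TN = sum(pred != k & obs != k),
                     FP = sum(pred == k & obs != k),
                     FN = sum(pred != k & obs == k))
  })
  names(out) <- as.character(classes)
  out
}

#' Accuracy from confusion counts or label vectors
#'
#' `(TP + TN) / (TP + TN + FP + FN)` for a `confusion_counts`; for two
#' label vectors, the fraction of positions predicted exactly right (Q3 /
#' Q15 when the labels are the 3- or 15-state tracks).
#'
#' @param c a `confusion_counts`, or the predicted label vector.
#' @param obs observed labels (vector form only).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(c, obs = NULL) {
  if (inherits(c, "confusion_counts")) {
    tot <- c$TP + c$TN + c$FP + c$FN
    if (tot == 0) stop("empty confusion counts")
    (c$TP + c$TN) / tot
  } else {
    stopifnot(!is.null(obs), length(c) == length(obs), length(obs) > 0)
    mean(c == obs)
  }
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning 0")
    return(0)
  }
  num / den
}

#' Precision, recall and F1 score
#'
#' `TP/(TP+FP)`, `TP/(TP+FN)` and `2TP/(2TP+FP+FN)`.  Degenerate
#' denominators return 0 with a warning so batch evaluation never aborts.
#'
#' @param c a `confusion_counts`.
#' @return Scalar metric in `[0, 1]`.
#' @export
precision <- function(c) .safe_ratio(c$TP, c$TP + c$FP, "precision")

#' @rdname precision
#' @export
recall <- function(c) .safe_ratio(c$TP, c$TP + c$FN, "recall")

#' @rdname precision
#' @export
f1 <- function(c) .safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN, "F1")

#' Pearson correlation between predicted and observed values
#'
#' @param pred,obs numeric vectors of equal length >= 2 with non-zero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("Pearson correlation undefined: zero variance")
  stats::cor(pred, obs)
}

#' Mean absolute error
#'
#' @param pred,obs numeric vectors of equal length.
#' @return Mean of `|pred - obs|`.
#' @export
mean_absolute_error <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) > 0)
  mean(abs(pred - obs))
}

#' Within-delta contact accuracy
#'
#' Fraction of residues whose predicted class differs from the observed
#' class by at most `delta`; at `delta = 0` this is the exact multi-class
#' accuracy.
#'
#' @param pred,obs integer class vectors of equal length.
#' @param delta non-negative tolerance on the class difference.
#' @return Fraction in `[0, 1]`.
#' @export
within_delta_accuracy <- function(pred, obs, delta = 2L) {
  stopifnot(length(pred) == length(obs), length(obs) > 0, delta >= 0)
  mean(abs(as.numeric(pred) - as.numeric(obs)) <= delta)
}

#' Full evaluation report
#'
#' Overall accuracy plus one-vs-rest precision/recall/F1 per class; for the
#' contact-number task also Pearson correlation, MAE and within-delta
#' accuracy on the class labels.
#'
#' @param pred,obs label vectors (integers for `cn15`, B/I/E for `sa3`).
#' @param task `"cn15"` or `"sa3"`.
#' @param delta tolerance for [within_delta_accuracy()] (cn15 only).
#' @return List with `overall` (named numerics) and `per_class`
#'   (data.frame).
#' @export
evaluate_predictions <- function(pred, obs, task = c("cn15", "sa3"),
                                 delta = 2L) {
  task <- match.arg(task)
  classes <- if (task == "sa3") c("B", "I", "E") else
    sort(unique(c(as.integer(obs), as.integer(pred))))
  cc <- confusion_by_class(pred, obs, classes)
  per_class <- data.frame(
    class = as.character(classes),
    precision = vapply(cc, precision, 0),
    recall = vapply(cc, recall, 0),
    f1 = vapply(cc, f1, 0),
    row.names = NULL)
  overall <- c(accuracy = accuracy(pred, obs))
  if (task == "cn15") {
    p <- as.numeric(pred); o <- as.numeric(obs)
    overall <- c(overall,
                 pcc = if (stats::sd(p) > 0 && stats::sd(o) > 0)
                   pearson_correlation(p, o) else NA_real_,
                 mae = mean_absolute_error(p, o),
                 within_delta = within_delta_accuracy(pred, obs, delta))
  }
  list(overall = overall, per_class = per_class)
}
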