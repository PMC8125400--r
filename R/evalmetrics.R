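# Discriminant-model evaluation: confusion matrix, accuracy, precision,
# recall, specificity, F1, ROC curves and AUC with one-vs-rest multiclass
# handling. Degenerate 0/0 denominators return 0 with a `degenerate`
# attribute instead of raising -- small test sets make them reachable.

#' Confusion matrix
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param classes ordered class labels; defaults to the order of first
#'   appearance in `c(y_true, y_pred)`. Unknown labels are an error.
#' @return k x k integer matrix (rows = true, columns = predicted) of
#'   class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_user("y_true and y_pred lengths differ")
  if (is.null(classes)) classes <- unique(c(y_true, y_pred))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop_user("label(s) not in 'classes': ", paste(bad, collapse = ", "))
  m <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

binary_counts <- function(cm, positive) {
  classes <- rownames(cm)
  if (!positive %in% classes)
    stop_user("'", positive, "' is not one of the classes")
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

ratio0 <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy` is the trace over the total; the per-class metrics reduce
#' the matrix to TP/FP/FN/TN counts with the named class as positive:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' and F1 the harmonic mean of precision and recall. A zero denominator
#' yields 0 carrying attribute `degenerate = TRUE`.
#'
#' @param cm a [confusion] matrix.
#' @param positive the positive class label.
#' @return a fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_user("empty confusion matrix")
  sum(diag(cm)) / total
}

#' @rdname accuracy
#' @export
precision <- function(cm, positive) {
  b <- binary_counts(cm, positive)
  ratio0(b["tp"], b["tp"] + b["fp"])
}

#' @rdname accuracy
#' @export
recall <- function(cm, positive) {
  b <- binary_counts(cm, positive)
  ratio0(b["tp"], b["tp"] + b["fn"])
}

#' @rdname accuracy
#' @export
specificity <- function(cm, positive) {
  b <- binary_counts(cm, positive)
  ratio0(b["tn"], b["tn"] + b["fp"])
}

#' @rdname accuracy
#' @export
f1 <- function(cm, positive) {
  p <- as.numeric(precision(cm, positive))
  r <- as.numeric(recall(cm, positive))
  if (p + r == 0) return(structure(0, degenerate = TRUE))
  2 * p * r / (p + r)
}

#' One-vs-rest metrics per class plus macro averages
#'
#' Each metric is computed one-vs-rest for every class; the macro average
#' is the unweighted mean (the cohorts this package targets are
#' near-balanced; micro-averaging is trivially the accuracy for
#' single-label problems).
#'
#' @param cm a [confusion] matrix with k >= 2 classes.
#' @return list with `per_class` (data.frame) and `macro` (named numeric:
#'   precision, recall, specificity, f1), plus `accuracy`.
#' @export
macro_metrics <- function(cm) {
  classes <- rownames(cm)
  if (length(classes) < 2L) stop_user("need >= 2 classes")
  per <- data.frame(
    class = classes,
    precision = vapply(classes, function(cl) as.numeric(precision(cm, cl)), 0),
    recall = vapply(classes, function(cl) as.numeric(recall(cm, cl)), 0),
    specificity = vapply(classes, function(cl)
      as.numeric(specificity(cm, cl)), 0),
    f1 = vapply(classes, function(cl) as.numeric(f1(cm, cl)), 0),
    row.names = NULL)
  list(accuracy = accuracy(cm), per_class = per,
       macro = c(precision = mean(per$precision), recall = mean(per$recall),
                 specificity = mean(per$specificity), f1 = mean(per$f1)))
}

#' ROC curve and AUC
#'
#' Thresholds are the descending unique scores with a sentinel above the
#' maximum; at each threshold a sample is called positive when its score
#' is >= the threshold. Tied scores collapse to one point (step-function
#' convention) and the AUC is the trapezoidal area under (FPR, TPR),
#' which equals the Mann-Whitney rank statistic.
#'
#' @param scores numeric scores, larger = more positive.
#' @param y_binary logical/0-1 truth (TRUE/1 = positive); both classes
#'   must be present.
#' @return object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`.
#' @export
roc_curve <- function(scores, y_binary) {
  y <- as.logical(y_binary)
  if (length(scores) != length(y))
    stop_user("scores and y_binary lengths differ")
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0L || nneg == 0L)
    stop_user("both classes must be present in y_binary")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yp <- y[o]
  cum_tp <- cumsum(yp); cum_fp <- cumsum(!yp)
  last_of_tie <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cum_tp[last_of_tie] / npos)
  fpr <- c(0, cum_fp[last_of_tie] / nneg)
  thresholds <- c(Inf, s[last_of_tie])
  auc <- trapz(fpr, tpr)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n",
              length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "False positive rate",
                 ylab = "True positive rate", xlim = c(0, 1),
                 ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' One-vs-rest ROC analysis for a multiclass probability matrix
#'
#' Each class's curve uses that class's probability column against the
#' one-vs-rest truth; the macro AUC is the unweighted mean over classes
#' present in `y_true` (absent classes are skipped with a warning).
#'
#' @param proba samples x classes probability matrix (rows sum to ~1);
#'   column names are the class labels.
#' @param y_true true labels.
#' @return list with `per_class` (named list of [roc_curve]s) and
#'   `macro_auc`.
#' @export
multiclass_roc <- function(proba, y_true) {
  proba <- as.matrix(proba)
  if (is.null(colnames(proba)))
    stop_user("'proba' needs class column names")
  y_true <- as.character(y_true)
  curves <- list()
  for (cl in colnames(proba)) {
    if (!cl %in% y_true) {
      warning("class '", cl, "' absent from y_true; skipped")
      next
    }
    curves[[cl]] <- roc_curve(proba[, cl], y_true == cl)
  }
  if (!length(curves)) stop_user("no class present in y_true")
  list(per_class = curves,
       macro_auc = mean(vapply(curves, `[[`, 0, "auc")))
}

#' Full evaluation report for a classifier on a test set
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param proba optional probability matrix for ROC analysis.
#' @param classes ordered class labels.
#' @return list with `confusion`, `metrics` ([macro_metrics]) and,
#'   when probabilities are given, `roc` ([multiclass_roc]).
#' @export
evaluate_classifier <- function(y_true, y_pred, proba = NULL,
                                classes = NULL) {
  cm <- confusion(y_true, y_pred, classes)
  out <- list(confusion = cm, metrics = macro_metrics(cm))
  if (!is.null(proba)) out$roc <- multiclass_roc(proba, y_true)
  out
}
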