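# Train/test protocol, grid-search cross-validation and comparator models
# (PLS-DA in-house; RBF-SVM and random forest delegated to e1071 and
# randomForest behind a uniform predict contract).

#' Stratified train/test split
#'
#' The default method splits a label vector and returns index sets; the
#' `peak_table` method returns two tables. Per-class test counts are
#' `round(n_class * test_fraction)`, so class proportions are preserved to
#' rounding and the split is disjoint and exhaustive.
#'
#' @param x label vector or [peak_table] (which must carry labels when
#'   `stratify = TRUE`).
#' @param test_fraction fraction of samples held out (default 0.33).
#' @param stratify preserve class proportions (default TRUE).
#' @param seed RNG seed; identical seeds give identical splits.
#' @param ... passed between methods.
#' @return default method: list with integer vectors `train` and `test`;
#'   `peak_table` method: list with two [peak_table]s.
#' @export
train_test_split <- function(x, test_fraction = 0.33, stratify = TRUE,
                             seed = 42, ...) {
  UseMethod("train_test_split")
}

#' @rdname train_test_split
#' @export
train_test_split.default <- function(x, test_fraction = 0.33,
                                     stratify = TRUE, seed = 42, ...) {
  n <- length(x)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_user("'test_fraction' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (stratify) {
    counts <- table(x)
    if (any(counts < 2L))
      stop_user("stratified split needs >= 2 samples per class; class(es) ",
                paste(names(counts)[counts < 2L], collapse = ", "),
                " too small")
    test <- integer(0)
    for (cl in names(counts)) {
      idx <- which(x == cl)
      n_test <- max(1L, round(length(idx) * test_fraction))
      test <- c(test, sort(sample(idx, n_test)))
    }
    test <- sort(test)
  } else {
    test <- sort(sample.int(n, max(1L, round(n * test_fraction))))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

#' @rdname train_test_split
#' @export
train_test_split.peak_table <- function(x, test_fraction = 0.33,
                                        stratify = TRUE, seed = 42, ...) {
  labels <- x$labels
  if (stratify && is.null(labels))
    stop_user("peak table has no labels; cannot stratify")
  y <- if (is.null(labels)) seq_along(x$sample_ids) else
    labels[x$sample_ids]
  idx <- train_test_split.default(if (stratify) y else x$sample_ids,
                                  test_fraction, stratify, seed)
  subset_tbl <- function(i) {
    tb <- peak_table(x$matrix[i, , drop = FALSE], x$features,
                     labels = if (is.null(labels)) NULL else
                       labels[x$sample_ids[i]],
                     normalized = x$normalized)
    tb
  }
  list(train = subset_tbl(idx$train), test = subset_tbl(idx$test),
       indices = idx)
}

#' Grid-search with stratified k-fold cross-validation
#'
#' Every row of `grid` is evaluated by stratified k-fold mean accuracy;
#' the best setting is the highest mean, ties resolved to the earlier grid
#' row. When `k_folds` exceeds the smallest class count it is reduced to
#' it with a warning (small cohorts are the norm here).
#'
#' @param x samples x features matrix.
#' @param y class labels.
#' @param grid data.frame of parameter combinations (one column per
#'   parameter).
#' @param model_factory `function(x, y, params)` returning a model whose
#'   `predict(model, x)` yields labels; defaults to [gbtree] with the
#'   grid row merged over its defaults.
#' @param k_folds folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return list with `best_params` (one-row data.frame), `best_accuracy`,
#'   and `cv_table` (grid plus `mean_accuracy`).
#' @export
grid_search_cv <- function(x, y, grid, model_factory = NULL, k_folds = 5,
                           seed = 42) {
  x <- as.matrix(x)
  y <- as.character(y)
  counts <- table(y)
  if (min(counts) < 2L)
    stop_user("cross-validation impossible: a class has < 2 samples; ",
              "use a smaller k or more data")
  if (k_folds > min(counts)) {
    warning("k_folds = ", k_folds, " exceeds smallest class count; using ",
            min(counts), " folds")
    k_folds <- min(counts)
  }
  if (k_folds < 2L) stop_user("k_folds must be >= 2")
  if (is.null(model_factory))
    model_factory <- function(x, y, params)
      do.call(gbtree, c(list(x = x, y = y), params))
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (cl in names(counts)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  acc <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    params <- as.list(grid[r, , drop = FALSE])
    hits <- 0L
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      model <- model_factory(x[tr, , drop = FALSE], y[tr], params)
      pred <- predict(model, x[!tr, , drop = FALSE])
      hits <- hits + sum(as.character(pred) == y[!tr])
    }
    acc[r] <- hits / length(y)
  }
  best <- which.max(acc)   # first max wins ties
  list(best_params = grid[best, , drop = FALSE], best_accuracy = acc[best],
       cv_table = cbind(grid, mean_accuracy = acc))
}

# ---- comparator models -----------------------------------------------------

# NIPALS PLS2 on one-hot class targets
fit_plsda <- function(x, y, n_components) {
  yf <- factor(y, levels = unique(as.character(y)))
  Y <- diag(nlevels(yf))[as.integer(yf), , drop = FALSE]
  colnames(Y) <- levels(yf)
  xm <- colMeans(x); ym <- colMeans(Y)
  E <- sweep(x, 2L, xm); Fm <- sweep(Y, 2L, ym)
  A <- min(n_components, ncol(x), nrow(x) - 1L)
  W <- matrix(0, ncol(x), A); P <- matrix(0, ncol(x), A)
  Q <- matrix(0, ncol(Y), A)
  for (a in seq_len(A)) {
    u <- Fm[, which.max(apply(Fm, 2L, var))]
    if (all(abs(u) < 1e-12)) break
    for (it in 1:500) {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      q <- crossprod(Fm, tt) / sum(tt^2)
      u_new <- Fm %*% q / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u^2)) { u <- u_new; break }
      u <- u_new
    }
    p <- crossprod(E, tt) / sum(tt^2)
    E <- E - tt %*% t(p)
    Fm <- Fm - tt %*% t(q)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q
  }
  B <- W %*% solve(t(P) %*% W, t(Q))
  list(B = B, xm = xm, ym = ym, classes = levels(yf))
}

#' Fit a comparator classifier
#'
#' Gives PLS-DA, RBF-kernel SVM and random forest the same predict
#' contract as [gbtree], so the downstream metric pipeline is identical
#' for every model. PLS-DA is an in-house NIPALS partial least squares on
#' one-hot targets with argmax decision; the SVM and random forest wrap
#' \pkg{e1071} and \pkg{randomForest}.
#'
#' @param kind `"plsda"`, `"svm_rbf"` or `"rf"`.
#' @param x samples x features matrix.
#' @param y class labels.
#' @param params named list of model parameters: `n_components` (plsda),
#'   `cost`/`gamma` (svm_rbf), `ntree`/`mtry` (rf).
#' @return object of class `comparator_model`.
#' @export
comparator_fit <- function(kind = c("plsda", "svm_rbf", "rf"), x, y,
                           params = list()) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.character(y)
  fit <- switch(kind,
    plsda = fit_plsda(x, y, params$n_components %||%
                        min(5L, ncol(x), nrow(x) - 1L)),
    svm_rbf = e1071::svm(x, factor(y, levels = unique(y)),
                         kernel = "radial", cost = params$cost %||% 1,
                         gamma = params$gamma %||% (1 / ncol(x)),
                         probability = TRUE),
    rf = {
      if (!is.null(params$seed)) set.seed(params$seed)
      randomForest::randomForest(x, factor(y, levels = unique(y)),
                                 ntree = params$ntree %||% 500L,
                                 mtry = params$mtry %||%
                                   max(1L, floor(sqrt(ncol(x)))))
    })
  structure(list(kind = kind, fit = fit,
                 classes = unique(y)),
            class = "comparator_model")
}

#' @export
predict.comparator_model <- function(object, newdata,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (object$kind == "plsda") {
    f <- object$fit
    yhat <- sweep(newdata, 2L, f$xm) %*% f$B
    yhat <- sweep(yhat, 2L, f$ym, "+")
    colnames(yhat) <- f$classes
    if (type == "prob") return(yhat)
    return(f$classes[apply(yhat, 1L, which.max)])
  }
  if (object$kind == "svm_rbf") {
    pr <- predict(object$fit, newdata, probability = TRUE)
    if (type == "class") return(as.character(pr))
    prob <- attr(pr, "probabilities")
    return(prob[, object$classes, drop = FALSE])
  }
  # rf
  if (type == "class")
    return(as.character(predict(object$fit, newdata)))
  predict(object$fit, newdata, type = "prob")[, object$classes,
                                              drop = FALSE]
}

#' @export
print.comparator_model <- function(x, ...) {
  cat("<comparator_model> ", x$kind, ", classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
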