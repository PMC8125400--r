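# Reference second-order gradient-boosted tree learner.
#
# The model is an additive ensemble: the prediction for sample i is the sum
# of K regression trees' outputs. Each boosting round expands the loss in a
# second-order Taylor series around the current scores; with per-sample
# gradient g_i and hessian h_i, a leaf's optimal weight is
# w = -G / (H + lambda) (G, H the leaf sums) and a split's improvement is
#
#   Gain = 1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda)
#                - (GL+GR)^2/(HL+HR+lambda) ] - gamma
#
# where gamma and lambda penalize leaf count and leaf weights. Split search
# is exact greedy over every (feature, midpoint-between-distinct-values)
# candidate; sparsity-aware and histogram approximations are deliberately
# out of scope (tables are filled upstream).

#' Gradients and hessians of the supported losses
#'
#' Softmax (multiclass log loss): `g = p - onehot(y)`, `h = p (1 - p)`.
#' Logistic: `g = sigmoid(s) - y`, `h = sigmoid(s) (1 - sigmoid(s))`.
#' Squared error (`l = (s - y)^2 / 2`): `g = s - y`, `h = 1`.
#'
#' @param loss one of `"softmax"`, `"logistic"`, `"squared"`.
#' @param y for softmax: integer class indices (1-based); for logistic:
#'   0/1; for squared: numeric targets.
#' @param raw_scores numeric matrix n x K (softmax) or vector (otherwise).
#' @return list with matrices/vectors `g` and `h` shaped like `raw_scores`.
#' @export
gradients_hessians <- function(loss, y, raw_scores) {
  switch(loss,
    softmax = {
      s <- raw_scores - apply(raw_scores, 1L, max)
      p <- exp(s) / rowSums(exp(s))
      onehot <- matrix(0, nrow(p), ncol(p))
      onehot[cbind(seq_len(nrow(p)), y)] <- 1
      list(g = p - onehot, h = p * (1 - p), proba = p)
    },
    logistic = {
      p <- 1 / (1 + exp(-raw_scores))
      list(g = p - y, h = p * (1 - p), proba = p)
    },
    squared = list(g = raw_scores - y, h = rep(1, length(y)), proba = NULL),
    stop_user("unknown loss '", loss, "'"))
}

#' Regularized split gain
#'
#' @param gl,hl gradient and hessian sums of the left child.
#' @param gr,hr gradient and hessian sums of the right child.
#' @param reg_lambda leaf-weight penalty lambda (>= 0).
#' @param gamma per-split penalty gamma (>= 0).
#' @return the gain (vectorized over its arguments).
#' @export
split_gain <- function(gl, hl, gr, hr, reg_lambda = 1, gamma = 0) {
  # a childless side contributes 0 (0/0 with lambda = 0), not NaN
  score <- function(g, h) {
    d <- h + reg_lambda
    ifelse(d == 0, 0, g^2 / d)
  }
  0.5 * (score(gl, hl) + score(gr, hr) - score(gl + gr, hl + hr)) - gamma
}

# exact greedy split over the active rows; ord = per-feature presorted row
# indices over the full training matrix
find_best_split <- function(x, g, h, rows, cols, ord, reg_lambda, gamma,
                            min_child_weight) {
  n <- nrow(x)
  member <- rep(FALSE, n)
  member[rows] <- TRUE
  best <- NULL
  for (j in cols) {
    idx <- ord[[j]]
    idx <- idx[member[idx]]
    if (length(idx) < 2L) next
    xv <- x[idx, j]
    splitpos <- which(diff(xv) > 0)
    if (!length(splitpos)) next
    cg <- cumsum(g[idx]); ch <- cumsum(h[idx])
    gt <- cg[length(cg)]; ht <- ch[length(ch)]
    gl <- cg[splitpos]; hl <- ch[splitpos]
    gr <- gt - gl; hr <- ht - hl
    ok <- hl >= min_child_weight & hr >= min_child_weight
    if (!any(ok)) next
    gains <- split_gain(gl, hl, gr, hr, reg_lambda, gamma)
    gains[!ok] <- -Inf
    b <- which.max(gains)               # lowest threshold wins ties in-feature
    if (is.null(best) || gains[b] > best$gain) {   # lowest feature index wins
      best <- list(feature = j,
                   threshold = (xv[splitpos[b]] + xv[splitpos[b] + 1L]) / 2,
                   gain = gains[b])
    }
  }
  best
}

#' Grow one regression tree by exact greedy split search
#'
#' @param x samples x features numeric matrix.
#' @param g,h per-sample gradients and hessians (one class's slice).
#' @param params list with `max_depth`, `reg_lambda`, `gamma`,
#'   `min_child_weight`.
#' @param rows row indices to grow on (subsample).
#' @param cols feature indices available to this tree (column sample).
#' @param ord optional list of presorted row orders per feature (computed
#'   if missing).
#' @return nested node list: internal nodes carry `feature`, `threshold`,
#'   `gain`, `left`, `right`; leaves carry `weight = -G / (H + lambda)`.
#' @export
build_tree <- function(x, g, h, params, rows = seq_len(nrow(x)),
                       cols = seq_len(ncol(x)), ord = NULL) {
  if (!length(rows)) stop_user("'rows' must be non-empty")
  if (is.null(ord))
    ord <- lapply(seq_len(ncol(x)), function(j) order(x[, j]))
  grow <- function(rows, depth) {
    G <- sum(g[rows]); H <- sum(h[rows])
    leaf <- list(leaf = TRUE, weight = -G / (H + params$reg_lambda),
                 cover = H)
    if (depth >= params$max_depth) return(leaf)
    best <- find_best_split(x, g, h, rows, cols, ord, params$reg_lambda,
                            params$gamma, params$min_child_weight)
    if (is.null(best) || best$gain <= 0) return(leaf)
    goleft <- x[rows, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         gain = best$gain,
         left = grow(rows[goleft], depth + 1L),
         right = grow(rows[!goleft], depth + 1L))
  }
  grow(rows, 0L)
}

# vectorized prediction: partition row indices down the tree
predict_tree <- function(node, x, rows = seq_len(nrow(x)),
                         out = numeric(nrow(x))) {
  if (node$leaf) {
    out[rows] <- node$weight
    return(out)
  }
  goleft <- x[rows, node$feature] <= node$threshold
  out <- predict_tree(node$left, x, rows[goleft], out)
  predict_tree(node$right, x, rows[!goleft], out)
}

tree_leaf_stats <- function(node) {
  if (node$leaf) return(c(n_leaves = 1, sum_w2 = node$weight^2))
  tree_leaf_stats(node$left) + tree_leaf_stats(node$right)
}

#' Fit a gradient-boosted tree model
#'
#' One tree per class per round for the softmax loss (the default for
#' classification); a single tree per round for squared-error regression.
#' The initial raw score is the log class prior (softmax) or the target
#' mean (squared). Row subsampling and per-tree column sampling draw from
#' the seeded RNG, so identical parameters and seed give an identical
#' model.
#'
#' @param x samples x features numeric matrix.
#' @param y class labels (factor/character/integer) for classification, or
#'   numeric targets with `loss = "squared"`.
#' @param loss `"softmax"` or `"squared"`.
#' @param n_estimators boosting rounds (trees per class).
#' @param learning_rate shrinkage in (0, 1].
#' @param max_depth maximum tree depth (>= 1).
#' @param gamma per-split complexity penalty (>= 0).
#' @param reg_lambda leaf-weight L2 penalty (>= 0).
#' @param min_child_weight minimum hessian sum per child (>= 0).
#' @param subsample row fraction per round in (0, 1].
#' @param colsample_bytree feature fraction per tree in (0, 1].
#' @param seed RNG seed.
#' @param verbose print the objective every 10 rounds.
#' @return an object of class `gbtree`: list with `classes`, `trees` (per
#'   class, one list of root nodes), `base_score`, `params`,
#'   `objective_trace` (the regularized training objective per round) and
#'   `feature_names`.
#' @export
gbtree <- function(x, y, loss = c("softmax", "squared"),
                   n_estimators = 100, learning_rate = 0.1, max_depth = 3,
                   gamma = 0, reg_lambda = 1, min_child_weight = 1,
                   subsample = 1, colsample_bytree = 1, seed = 42,
                   verbose = FALSE) {
  loss <- match.arg(loss)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (learning_rate <= 0 || learning_rate > 1)
    stop_user("'learning_rate' must be in (0, 1]")
  if (subsample <= 0 || subsample > 1)
    stop_user("'subsample' must be in (0, 1]")
  if (colsample_bytree <= 0 || colsample_bytree > 1)
    stop_user("'colsample_bytree' must be in (0, 1]")
  params <- list(loss = loss, n_estimators = n_estimators,
                 learning_rate = learning_rate, max_depth = max_depth,
                 gamma = gamma, reg_lambda = reg_lambda,
                 min_child_weight = min_child_weight, subsample = subsample,
                 colsample_bytree = colsample_bytree, seed = seed)
  if (!is.null(seed)) set.seed(seed)
  ord <- lapply(seq_len(p), function(j) order(x[, j]))

  if (loss == "softmax") {
    yf <- factor(y, levels = unique(as.character(y)))
    classes <- levels(yf)
    K <- length(classes)
    if (K < 2L) stop_user("classification needs >= 2 classes in 'y'")
    yi <- as.integer(yf)
    base <- log(as.numeric(table(yi)) / n)
    scores <- matrix(base, n, K, byrow = TRUE)
  } else {
    classes <- NULL
    K <- 1L
    yi <- as.numeric(y)
    base <- mean(yi)
    scores <- matrix(base, n, 1L)
  }

  trees <- rep(list(list()), K)
  obj_trace <- numeric(n_estimators)
  omega_cum <- 0
  n_sub <- max(1L, round(subsample * n))
  p_sub <- max(1L, round(colsample_bytree * p))
  for (t in seq_len(n_estimators)) {
    gh <- gradients_hessians(loss, yi, if (K == 1L) scores[, 1L] else scores)
    rows <- if (n_sub < n) sort(sample.int(n, n_sub)) else seq_len(n)
    for (k in seq_len(K)) {
      cols <- if (p_sub < p) sort(sample.int(p, p_sub)) else seq_len(p)
      gk <- if (K == 1L) gh$g else gh$g[, k]
      hk <- if (K == 1L) gh$h else gh$h[, k]
      tree <- build_tree(x, gk, hk, params, rows = rows, cols = cols,
                         ord = ord)
      trees[[k]][[t]] <- tree
      scores[, k] <- scores[, k] + learning_rate * predict_tree(tree, x)
      st <- tree_leaf_stats(tree)
      # the sub-model added to the ensemble is the shrunk tree, so the
      # regularizer penalizes the effective leaf weights lr * w
      omega_cum <- omega_cum + gamma * st[["n_leaves"]] +
        0.5 * reg_lambda * learning_rate^2 * st[["sum_w2"]]
    }
    l_now <- if (loss == "softmax") {
      s <- scores - apply(scores, 1L, max)
      pmat <- exp(s) / rowSums(exp(s))
      -sum(log(pmax(pmat[cbind(seq_len(n), yi)], 1e-300)))
    } else {
      0.5 * sum((scores[, 1L] - yi)^2)
    }
    obj_trace[t] <- l_now + omega_cum
    if (verbose && t %% 10L == 0L)
      message(sprintf("round %d: objective %.4f", t, obj_trace[t]))
  }
  structure(list(classes = classes, trees = trees, base_score = base,
                 params = params, objective_trace = obj_trace,
                 feature_names = colnames(x) %||%
                   paste0("f", seq_len(p)), n_features = p),
            class = "gbtree")
}

gbtree_raw_scores <- function(object, x) {
  K <- max(1L, length(object$classes))
  scores <- matrix(object$base_score, nrow(x), K, byrow = TRUE)
  lr <- object$params$learning_rate
  for (k in seq_len(K))
    for (tree in object$trees[[k]])
      scores[, k] <- scores[, k] + lr * predict_tree(tree, x)
  scores
}

#' Predict from a fitted gbtree model
#'
#' @param object a fitted [gbtree] model.
#' @param newdata samples x features matrix with the training feature
#'   count.
#' @param type `"class"` (labels; probability ties go to the first class in
#'   training order), `"prob"` (softmax class probabilities) or `"raw"`
#'   (accumulated raw scores).
#' @param ... unused.
#' @return labels, a probability matrix, or a raw-score matrix.
#' @export
predict.gbtree <- function(object, newdata,
                           type = c("class", "prob", "raw"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop_user("newdata has ", ncol(newdata), " features; model expects ",
              object$n_features)
  scores <- gbtree_raw_scores(object, newdata)
  if (object$params$loss == "squared") {
    return(if (type == "raw") scores else scores[, 1L])
  }
  if (type == "raw") return(scores)
  s <- scores - apply(scores, 1L, max)
  proba <- exp(s) / rowSums(exp(s))
  colnames(proba) <- object$classes
  if (type == "prob") return(proba)
  object$classes[apply(proba, 1L, which.max)]
}

#' @export
print.gbtree <- function(x, ...) {
  K <- max(1L, length(x$classes))
  cat("<gbtree> ", x$params$loss, " loss, ", length(x$trees[[1L]]),
      " rounds x ", K, if (is.null(x$classes)) " tree" else
        " classes", ", depth <= ", x$params$max_depth, "\n", sep = "")
  if (!is.null(x$classes))
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  final training objective: %.4f\n",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' @export
summary.gbtree <- function(object, ...) {
  imp <- feature_importance(object)
  cat("Gradient-boosted tree ensemble\n")
  print(object)
  cat("  top features by total split gain:\n")
  top <- head(imp[imp > 0], 10L)
  for (i in seq_along(top))
    cat(sprintf("    %-12s %.4g\n", names(top)[i], top[i]))
  invisible(list(importance = imp,
                 objective_trace = object$objective_trace))
}

collect_gains <- function(node, acc) {
  if (node$leaf) return(acc)
  acc[node$feature] <- acc[node$feature] + node$gain
  acc <- collect_gains(node$left, acc)
  collect_gains(node$right, acc)
}

#' Feature importance by total split gain
#'
#' Sums the regularized gain over every internal node that splits on each
#' feature, across all trees and classes. Unused features score 0.
#'
#' @param model a fitted [gbtree].
#' @return named numeric vector over all features, descending.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "gbtree"))
  acc <- setNames(numeric(model$n_features), model$feature_names)
  for (cls in model$trees)
    for (tree in cls)
      acc <- collect_gains(tree, acc)
  sort(acc, decreasing = TRUE)
}

#' Serialize / restore a gbtree model as JSON
#'
#' Trees are stored as nested objects, so models survive a round trip
#' exactly (up to double-precision printing, which is kept at full
#' precision).
#'
#' @param model a fitted [gbtree].
#' @param path output path.
#' @return `path` (write) or the restored `gbtree` (read).
#' @export
write_gbtree <- function(model, path) {
  stopifnot(inherits(model, "gbtree"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = FALSE)
  invisible(path)
}

relist_node <- function(node) {
  if (isTRUE(node$leaf))
    return(list(leaf = TRUE, weight = node$weight, cover = node$cover))
  list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
       gain = node$gain, left = relist_node(node$left),
       right = relist_node(node$right))
}

#' @rdname write_gbtree
#' @export
read_gbtree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  obj$trees <- lapply(obj$trees, function(cls) lapply(cls, relist_node))
  obj$base_score <- as.numeric(obj$base_score)
  obj$objective_trace <- as.numeric(obj$objective_trace)
  obj$feature_names <- as.character(obj$feature_names)
  obj$classes <- if (is.null(obj$classes)) NULL else as.character(obj$classes)
  structure(obj, class = "gbtree")
}
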