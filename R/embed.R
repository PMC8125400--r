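# 2-D visualization of feature tables. PCA is computed from first
# principles (column-centered SVD); t-SNE and UMAP are delegated to the
# established Rtsne and uwot implementations, with contracts limited to
# shape, finiteness and seeded reproducibility -- the package uses them for
# visualization only.

new_embedding <- function(method, coords, params,
                          explained_variance = NULL) {
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(list(method = method, coords = coords, params = params,
                 explained_variance = explained_variance),
            class = "ms_embedding")
}

#' @export
print.ms_embedding <- function(x, ...) {
  cat("<ms_embedding> ", x$method, ": ", nrow(x$coords), " samples x ",
      ncol(x$coords), " dims", sep = "")
  if (!is.null(x$explained_variance))
    cat(sprintf("; var explained %.1f%%",
                100 * sum(x$explained_variance[seq_len(ncol(x$coords))])))
  cat("\n")
  invisible(x)
}

as_embed_matrix <- function(x) {
  if (inherits(x, "peak_table")) x$matrix else as.matrix(x)
}

#' Principal component analysis embedding
#'
#' Column-centered singular value decomposition; coordinates are the
#' projections on the leading components. Sign convention: the
#' largest-magnitude loading of each component is made positive, so the
#' embedding is reproducible across platforms up to that fixed choice.
#'
#' @param x samples x features matrix or [peak_table].
#' @param n_components number of components to keep (default 2).
#' @return an `ms_embedding`; `explained_variance` holds the per-component
#'   variance fractions for all components (non-increasing, summing to 1).
#' @export
pca_embed <- function(x, n_components = 2) {
  m <- as_embed_matrix(x)
  if (nrow(m) < 2L) stop_user("PCA needs at least 2 samples")
  if (ncol(m) < 2L) stop_user("PCA needs at least 2 features")
  mc <- sweep(m, 2L, colMeans(m), "-")
  sv <- svd(mc)
  for (j in seq_along(sv$d)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  ev <- sv$d^2
  ev <- if (sum(ev) > 0) ev / sum(ev) else ev
  k <- min(n_components, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- rownames(m)
  new_embedding("pca", coords, list(n_components = n_components),
                explained_variance = ev)
}

#' t-SNE embedding (delegated to Rtsne)
#'
#' @param x samples x features matrix or [peak_table].
#' @param perplexity neighbourhood size; default `min(30, (n - 1) / 3)`.
#'   Must be below the number of samples.
#' @param seed RNG seed; identical seeds reproduce coordinates exactly.
#' @return an `ms_embedding` with 2-D coordinates.
#' @export
tsne_embed <- function(x, perplexity = NULL, seed = 42) {
  m <- as_embed_matrix(x)
  n <- nrow(m)
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  if (perplexity >= n)
    stop_user("perplexity (", perplexity, ") must be < n_samples (", n, ")")
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2L, perplexity = perplexity, theta = 0,
                      check_duplicates = FALSE, pca = FALSE,
                      max_iter = 1000L)
  coords <- fit$Y
  rownames(coords) <- rownames(m)
  new_embedding("tsne", coords,
                list(perplexity = perplexity, seed = seed))
}

#' UMAP embedding (delegated to uwot)
#'
#' @param x samples x features matrix or [peak_table].
#' @param n_neighbors local neighbourhood size, `2 <= n_neighbors < n`.
#'   Larger values favour global structure.
#' @param min_dist minimum spacing of embedded points; smaller values give
#'   tighter clusters.
#' @param seed RNG seed; runs are single-threaded so identical seeds
#'   reproduce coordinates exactly.
#' @return an `ms_embedding` with 2-D coordinates.
#' @export
umap_embed <- function(x, n_neighbors = 15, min_dist = 0.1, seed = 42) {
  m <- as_embed_matrix(x)
  n <- nrow(m)
  if (n_neighbors < 2 || n_neighbors >= n)
    stop_user("n_neighbors must satisfy 2 <= n_neighbors < n_samples (",
              n, ")")
  set.seed(seed)
  coords <- uwot::umap(m, n_neighbors = n_neighbors, min_dist = min_dist,
                       n_components = 2L, n_threads = 1L,
                       n_sgd_threads = 0L, init = "pca",
                       init_sdev = "range", verbose = FALSE)
  rownames(coords) <- rownames(m)
  new_embedding("umap", coords,
                list(n_neighbors = n_neighbors, min_dist = min_dist,
                     seed = seed))
}

#' Scatter plot of an embedding colored by class
#'
#' @param x an `ms_embedding`.
#' @param labels optional named or positional class labels.
#' @param ... passed to [graphics::plot].
#' @export
plot.ms_embedding <- function(x, labels = NULL, ...) {
  cols <- 1
  if (!is.null(labels)) {
    if (!is.null(names(labels)) && !is.null(rownames(x$coords)))
      labels <- labels[rownames(x$coords)]
    cols <- as.integer(factor(labels)) + 1L
  }
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = cols, pch = 19,
                 xlab = paste(x$method, "1"), ylab = paste(x$method, "2"),
                 ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_len(nlevels(factor(labels))) + 1L, pch = 19,
                     cex = 0.8)
  invisible(x)
}

#' Write embedding coordinates as CSV
#'
#' @param embedding an `ms_embedding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(sample_id = rownames(embedding$coords) %||%
                     seq_len(nrow(embedding$coords)),
                   embedding$coords)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
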