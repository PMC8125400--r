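# helpers shared across the test files; everything is generated in code

# a PIC object built directly from rt/intensity vectors (0.5 s scans)
make_pic <- function(rt, intensity, mz = 500, pic_id = 1L) {
  keep <- intensity > 0
  pts <- data.frame(scan_index = as.integer(round(rt / 0.5))[keep],
                    rt = rt[keep], mz = rep(mz, sum(keep)),
                    intensity = intensity[keep])
  picboost:::new_pic(pts, "test", pic_id)
}

gaussian_trace <- function(rt, apex, sigma, height)
  height * exp(-(rt - apex)^2 / (2 * sigma^2))

# two well-separated Gaussian clusters in feature space
two_cluster_data <- function(n_per = 15, p = 20, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per))
  list(x = x, labels = rep(c("a", "b"), each = n_per))
}

mean_silhouette <- function(coords, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dmatrix = as.matrix(dist(coords)))
  mean(sil[, 3])
}

# minimal mzXML 3.x writer (base64 network-order doubles, m/z-int pairs)
write_test_mzxml <- function(path, rts, mzs, ints) {
  enc <- function(mz, inten) {
    v <- as.numeric(rbind(mz, inten))
    gsub("\n", "", jsonlite::base64_enc(writeBin(v, raw(), size = 8L,
                                                 endian = "big")),
         fixed = TRUE)
  }
  scans <- vapply(seq_along(rts), function(i) {
    paste0('<scan num="', i, '" msLevel="1" peaksCount="',
           length(mzs[[i]]), '" retentionTime="PT', rts[i],
           'S" centroided="1">',
           '<peaks precision="64" byteOrder="network" ',
           'contentType="m/z-int" compressionType="none" ',
           'compressedLen="0">', enc(mzs[[i]], ints[[i]]),
           '</peaks></scan>')
  }, character(1))
  writeLines(paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/',
    'mzXML_3.2">\n<msRun scanCount="', length(rts), '">\n',
    paste0(scans, collapse = "\n"), '\n</msRun>\n</mzXML>'), path)
  path
}

# count internal nodes of a gbtree model
n_internal_nodes <- function(model) {
  count <- function(node) {
    if (node$leaf) return(0L)
    1L + count(node$left) + count(node$right)
  }
  sum(vapply(unlist(model$trees, recursive = FALSE), count, 0L))
}

# brute-force best regularized split over all features and midpoints
oracle_best_gain <- function(x, g, h, lambda, gamma) {
  best <- -Inf
  for (j in seq_len(ncol(x))) {
    xs <- sort(unique(x[, j]))
    if (length(xs) < 2L) next
    for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
      left <- x[, j] <= thr
      gain <- 0.5 * (sum(g[left])^2 / (sum(h[left]) + lambda) +
                       sum(g[!left])^2 / (sum(h[!left]) + lambda) -
                       sum(g)^2 / (sum(h) + lambda)) - gamma
      if (gain > best) best <- gain
    }
  }
  best
}

# brute-force least-squares decision stump SSE
oracle_stump_sse <- function(x, y) {
  best <- sum((y - mean(y))^2)
  for (j in seq_len(ncol(x))) {
    xs <- sort(unique(x[, j]))
    if (length(xs) < 2L) next
    for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
      left <- x[, j] <= thr
      sse <- sum((y[left] - mean(y[left]))^2) +
        sum((y[!left] - mean(y[!left]))^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Mann-Whitney AUC: fraction of (pos, neg) pairs ranked correctly
mann_whitney_auc <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# small helper for matching detected peaks/groups against planted truth
match_truth <- function(truth_mz, truth_rt, cand_mz, cand_rt,
                        ppm = 10, rt_tol = 5) {
  vapply(seq_along(truth_mz), function(i)
    sum(abs(cand_mz - truth_mz[i]) <= ppm * 1e-6 * truth_mz[i] &
          abs(cand_rt - truth_rt[i]) <= rt_tol), 0L)
}
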