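#' Parameters for pure ion chromatogram extraction
#'
#' @param mz_tol_ppm relative m/z tolerance in ppm. A cluster is accepted as
#'   pure when its maximum deviation from the intensity-weighted mean m/z is
#'   within this tolerance (so the full observed m/z range spans at most
#'   twice the tolerance).
#' @param coarse_width width (Da) of the coarse m/z slabs used to seed
#'   candidate regions before clustering.
#' @param min_length minimum number of scans with signal per PIC (>= 3).
#' @param max_gap maximum run of consecutive empty scans tolerated inside a
#'   PIC; longer gaps split the trace.
#' @param min_apex minimum apex intensity; `NULL` (default) resolves at
#'   extraction time to 3x the run's median non-zero intensity.
#' @return list of class `pic_params`.
#' @export
pic_params <- function(mz_tol_ppm = 15, coarse_width = 0.1, min_length = 5,
                       max_gap = 2, min_apex = NULL) {
  check_positive(mz_tol_ppm, "mz_tol_ppm")
  check_positive(coarse_width, "coarse_width")
  check_positive(min_length, "min_length")
  if (min_length < 3) stop_user("'min_length' must be >= 3")
  check_positive(max_gap + 1, "max_gap")  # max_gap >= 0 allowed
  if (!is.null(min_apex)) check_positive(min_apex, "min_apex")
  structure(list(mz_tol_ppm = mz_tol_ppm, coarse_width = coarse_width,
                 min_length = as.integer(min_length),
                 max_gap = as.integer(max_gap), min_apex = min_apex),
            class = "pic_params")
}

#' Partition ion points into candidate m/z regions
#'
#' Points are sliced into coarse m/z slabs of width `coarse_width`;
#' neighbouring slabs whose nearest points lie closer than `coarse_width/2`
#' are merged (single linkage), so a trace straddling a slab boundary stays
#' in one region. Every input point lands in exactly one region.
#'
#' @param points data.frame of ion points as returned by [to_points].
#' @param params a [pic_params] object.
#' @return list of point data.frames, ascending in m/z.
#' @export
find_regions <- function(points, params = pic_params()) {
  if (nrow(points) == 0L) return(list())
  o <- order(points$mz)
  mz <- points$mz[o]
  slab <- floor(mz / params$coarse_width)
  gap <- diff(mz)
  newreg <- c(TRUE, diff(slab) != 0 & gap >= params$coarse_width / 2)
  region_id <- cumsum(newreg)
  regions <- split(points[o, , drop = FALSE], region_id)
  names(regions) <- NULL
  regions
}

# deterministic 2-means on the m/z coordinate with intensity-weighted
# centroid updates; centers start at the two extreme m/z values
kmeans2_mz <- function(mz, intensity, max_iter = 100L) {
  c1 <- min(mz); c2 <- max(mz)
  left <- mz - c1 <= c2 - mz          # ties go left
  for (it in seq_len(max_iter)) {
    c1 <- weighted.mean(mz[left], intensity[left])
    c2 <- weighted.mean(mz[!left], intensity[!left])
    new_left <- abs(mz - c1) <= abs(mz - c2)
    if (all(new_left == left)) break
    if (all(new_left) || !any(new_left)) break  # degenerate; keep previous
    left <- new_left
  }
  left
}

weighted_sd <- function(x, w) {
  if (length(x) < 2L) return(0)
  m <- weighted.mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# iteratively drop the point farthest from the intensity-weighted mean
# until the relative spread is within tolerance (jitter-outlier trimming
# for unimodal clusters)
trim_to_tol <- function(r, tol) {
  repeat {
    wm <- weighted.mean(r$mz, r$intensity)
    dev <- abs(r$mz - wm)
    if (nrow(r) == 1L || max(dev) / wm <= tol) return(r)
    r <- r[-which.max(dev), , drop = FALSE]
  }
}

#' Split a candidate region into pure m/z clusters
#'
#' Recursive bisection: a region whose relative m/z spread (maximum
#' deviation from the intensity-weighted mean, divided by that mean) is
#' within `mz_tol_ppm` is returned as one cluster; otherwise a
#' deterministic 2-means on m/z (centers initialized at the extreme m/z
#' values, centroids updated with intensity weights) proposes a split.
#' The split is accepted -- and both children processed recursively --
#' only when the two children are genuinely separated populations (center
#' distance at least 4x the larger within-child spread); otherwise the
#' region is a single ion whose m/z jitter happens to exceed the
#' tolerance, and the few outlying points are trimmed instead of
#' fragmenting the trace in time. Each accepted split strictly shrinks the
#' children, so the recursion terminates.
#'
#' @param region data.frame of ion points (non-empty).
#' @param params a [pic_params] object.
#' @return list of point data.frames.
#' @export
split_region <- function(region, params = pic_params()) {
  if (nrow(region) == 0L) stop_user("'region' is empty")
  tol <- params$mz_tol_ppm * 1e-6
  out <- vector("list", 0L)
  queue <- list(region)
  while (length(queue)) {
    r <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    wm <- weighted.mean(r$mz, r$intensity)
    if (nrow(r) == 1L || max(abs(r$mz - wm)) / wm <= tol ||
        length(unique(r$mz)) == 1L) {
      out[[length(out) + 1L]] <- r
      next
    }
    left <- kmeans2_mz(r$mz, r$intensity)
    if (all(left) || !any(left)) {     # safeguard: bisect at midpoint
      mid <- (min(r$mz) + max(r$mz)) / 2
      left <- r$mz <= mid
    }
    c1 <- weighted.mean(r$mz[left], r$intensity[left])
    c2 <- weighted.mean(r$mz[!left], r$intensity[!left])
    s <- max(weighted_sd(r$mz[left], r$intensity[left]),
             weighted_sd(r$mz[!left], r$intensity[!left]))
    if (abs(c2 - c1) < 4 * s) {
      # unimodal: one ion with heavy-tailed jitter -- trim outliers
      out[[length(out) + 1L]] <- trim_to_tol(r, tol)
      next
    }
    queue[[length(queue) + 1L]] <- r[left, , drop = FALSE]
    queue[[length(queue) + 1L]] <- r[!left, , drop = FALSE]
  }
  out
}

#' Enforce one intensity per scan within a cluster
#'
#' For each scan the highest-intensity point is kept; intensity ties are
#' broken by the m/z nearest the cluster's intensity-weighted mean, then by
#' the lowest m/z.
#'
#' @param cluster data.frame of ion points (non-empty).
#' @return data.frame with at most one row per `scan_index`, ordered by scan.
#' @export
resolve_scan_duplicates <- function(cluster) {
  if (nrow(cluster) == 0L) stop_user("'cluster' is empty")
  wm <- weighted.mean(cluster$mz, cluster$intensity)
  o <- order(cluster$scan_index, -cluster$intensity,
             abs(cluster$mz - wm), cluster$mz)
  cl <- cluster[o, , drop = FALSE]
  cl <- cl[!duplicated(cl$scan_index), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

new_pic <- function(points, sample_id, pic_id = NA_integer_) {
  wm <- weighted.mean(points$mz, points$intensity)
  structure(list(pic_id = pic_id, sample_id = sample_id, points = points,
                 mz_mean = wm, mz_lo = min(points$mz), mz_hi = max(points$mz)),
            class = "pic")
}

#' @export
print.pic <- function(x, ...) {
  cat(sprintf("<pic #%s> m/z %.4f [%.4f-%.4f], %d scans, rt %.1f-%.1f s, apex %.3g\n",
              x$pic_id, x$mz_mean, x$mz_lo, x$mz_hi, nrow(x$points),
              min(x$points$rt), max(x$points$rt), max(x$points$intensity)))
  invisible(x)
}

# split one-per-scan points at gaps of empty scans longer than max_gap
split_at_gaps <- function(points, max_gap) {
  if (nrow(points) <= 1L) return(list(points))
  brk <- c(FALSE, diff(points$scan_index) > max_gap + 1L)
  unname(split(points, cumsum(brk)))
}

#' Extract pure ion chromatograms from a run
#'
#' Pipeline: [find_regions] (coarse m/z slabs) -> [split_region] (bisecting
#' 2-means until each cluster is within the ppm tolerance) ->
#' [resolve_scan_duplicates] (one intensity per scan) -> split at scan gaps
#' longer than `max_gap` -> drop traces shorter than `min_length` scans or
#' with apex below `min_apex`. Gaps that survive are kept as absent scans
#' (no zero filling), so peak detection sees the true sampling. The whole
#' procedure is deterministic: identical input and parameters give
#' identical PICs.
#'
#' @param run an [ms_run].
#' @param params a [pic_params] object.
#' @return list of `pic` objects numbered in `(mz_mean, first rt)` order,
#'   with class `pic_list`.
#' @export
extract_pics <- function(run, params = pic_params()) {
  stopifnot(inherits(run, "ms_run"))
  pts <- to_points(run)
  min_apex <- params$min_apex
  if (is.null(min_apex)) {
    nz <- pts$intensity[pts$intensity > 0]
    min_apex <- if (length(nz)) 3 * median(nz) else 0
  }
  regions <- find_regions(pts, params)
  pics <- list()
  for (reg in regions) {
    if (nrow(reg) < params$min_length) next   # cannot yield a long-enough PIC
    for (cl in split_region(reg, params)) {
      if (nrow(cl) < params$min_length) next
      pp <- resolve_scan_duplicates(cl)
      for (seg in split_at_gaps(pp, params$max_gap)) {
        if (nrow(seg) < params$min_length) next
        if (max(seg$intensity) < min_apex) next
        pics[[length(pics) + 1L]] <- new_pic(seg, run$sample_id)
      }
    }
  }
  if (length(pics)) {
    key_mz <- vapply(pics, `[[`, 0, "mz_mean")
    key_rt <- vapply(pics, function(p) p$points$rt[1L], 0)
    o <- order(key_mz, key_rt)
    pics <- pics[o]
    for (i in seq_along(pics)) pics[[i]]$pic_id <- i
  }
  structure(pics, class = "pic_list", sample_id = run$sample_id)
}

#' @export
print.pic_list <- function(x, ...) {
  cat("<pic_list> ", length(x), " PICs from sample '",
      attr(x, "sample_id"), "'\n", sep = "")
  invisible(x)
}

#' Flatten a list of PICs to a long table
#'
#' @param x a `pic_list` (or plain list of `pic` objects).
#' @param ... unused.
#' @return data.frame with columns `pic_id`, `scan_index`, `rt`, `mz`,
#'   `intensity`, suitable for CSV dump and plotting.
#' @export
as.data.frame.pic_list <- function(x, ...) {
  if (!length(x))
    return(data.frame(pic_id = integer(0), scan_index = integer(0),
                      rt = numeric(0), mz = numeric(0),
                      intensity = numeric(0)))
  do.call(rbind, lapply(x, function(p)
    cbind(pic_id = p$pic_id, p$points[c("scan_index", "rt", "mz", "intensity")])))
}
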