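# Chromatographic peak detection on pure ion chromatograms.
#
# A PIC is resampled onto a uniform RT grid (linear interpolation across
# gaps), transformed with a Mexican-hat continuous wavelet over a set of
# scales, and ridge lines linked across scales locate peak apexes. The
# wavelet has zero mean, so detection is invariant to a constant baseline,
# and the SNR is a ratio of two intensity-scaled quantities, so it is
# invariant to multiplying all intensities by a constant.

mexican_hat <- function(t) (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)

# CWT row for one scale (in grid points); positive response at peaks
cwt_row <- function(y, scale_pts) {
  half <- max(1L, ceiling(5 * scale_pts))
  tt <- seq(-half, half) / scale_pts
  kern <- mexican_hat(tt) / sqrt(scale_pts)
  n <- length(y)
  ypad <- c(rep(y[1L], half), y, rep(y[n], half))
  out <- convolve(ypad, kern, type = "filter")
  out[seq_len(n)]
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
          v[2:(n - 1)] > 0) + 1L
}

# link per-scale maxima into ridges, walking from the largest scale down
link_ridges <- function(max_by_scale, scale_pts) {
  ns <- length(max_by_scale)
  ridges <- list()   # each: list(pos = current position, hits = (scale, pos))
  for (s in rev(seq_len(ns))) {
    cand <- max_by_scale[[s]]
    win <- max(2, scale_pts[s])
    used <- rep(FALSE, length(cand))
    for (r in seq_along(ridges)) {
      if (!length(cand)) break
      d <- abs(cand - ridges[[r]]$pos)
      j <- which.min(d)
      if (!used[j] && d[j] <= win) {
        used[j] <- TRUE
        ridges[[r]]$pos <- cand[j]
        ridges[[r]]$hits <- rbind(ridges[[r]]$hits, c(s, cand[j]))
      }
    }
    for (j in which(!used))
      ridges[[length(ridges) + 1L]] <-
        list(pos = cand[j], hits = matrix(c(s, cand[j]), 1L))
  }
  ridges
}

# walk outward from an apex on a lightly smoothed signal to the nearest
# flanking local minimum or (near-)zero crossing; fall back to the ends
find_bounds <- function(y_s, apex, eps) {
  n <- length(y_s)
  left <- apex
  while (left > 1L) {
    if (y_s[left - 1L] > y_s[left] && y_s[left] <= y_s[min(left + 1L, n)]) break
    if (y_s[left - 1L] <= eps) { left <- left - 1L; break }
    left <- left - 1L
  }
  right <- apex
  while (right < n) {
    if (y_s[right + 1L] > y_s[right] && y_s[right] <= y_s[max(right - 1L, 1L)]) break
    if (y_s[right + 1L] <= eps) { right <- right + 1L; break }
    right <- right + 1L
  }
  c(left, right)
}

moving_avg <- function(y, w) {
  if (w < 3L) return(y)
  if (w %% 2L == 0L) w <- w + 1L
  half <- w %/% 2L
  ypad <- c(rep(y[1L], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(ypad, rep(1 / w, w), sides = 2L))[
    (half + 1L):(half + length(y))]
}

#' Detect chromatographic peaks on a PIC
#'
#' Continuous wavelet transform with a Mexican-hat wavelet over `scales`
#' (seconds); local maxima of each scale row are linked into ridge lines;
#' each ridge's apex is placed at the raw-signal maximum near the strongest
#' ridge response. Peak boundaries are the nearest flanking local minima
#' (on a lightly smoothed signal) or effective zero-crossings, falling back
#' to the PIC end points. The noise level is the (variance-calibrated)
#' median absolute deviation of the residual left after subtracting a
#' 3-point local smooth, floored at 1 count; SNR is the
#' baseline-corrected apex height over that noise. Both the wavelet and
#' the residual are insensitive to a constant baseline, and SNR is a
#' ratio of intensity-scaled quantities, so detection is invariant to
#' baseline shifts and intensity rescaling.
#'
#' @param pic a `pic` object (at least `min_length` points).
#' @param scales wavelet scales in seconds; default 8 log-spaced values
#'   between 2 and 30 s.
#' @param snr_min minimum signal-to-noise ratio (default 3).
#' @return data.frame of peaks in RT order with columns `pic_id`, `mz`,
#'   `rt_apex`, `rt_left`, `rt_right`, `height`, `area`, `snr`.
#' @export
detect_peaks <- function(pic, scales = NULL, snr_min = 3) {
  stopifnot(inherits(pic, "pic"))
  if (is.null(scales)) scales <- exp(seq(log(2), log(30), length.out = 8))
  pts <- pic$points
  empty <- data.frame(pic_id = integer(0), mz = numeric(0),
                      rt_apex = numeric(0), rt_left = numeric(0),
                      rt_right = numeric(0), height = numeric(0),
                      area = numeric(0), snr = numeric(0))
  if (nrow(pts) < 3L) return(empty)
  dt <- median(diff(pts$rt))
  grid <- seq(pts$rt[1L], pts$rt[nrow(pts)], by = dt)
  y <- approx(pts$rt, pts$intensity, xout = grid, rule = 2)$y
  n <- length(y)
  if (n < 5L || max(y) == min(y)) return(empty)

  scale_pts <- pmax(1, scales / dt)
  cwt <- lapply(scale_pts, function(s) cwt_row(y, s))
  # noise = spread of the residual against a 3-point local smooth;
  # sqrt(3/2) calibrates the residual variance back to the point noise.
  # Floored at 1 count so noiseless synthetic signals keep a finite SNR.
  noise <- max(1.0, mad(y - moving_avg(y, 3L)) * sqrt(3 / 2))
  max_by_scale <- lapply(cwt, local_maxima)
  ridges <- link_ridges(max_by_scale, scale_pts)

  rows <- list()
  for (rg in ridges) {
    if (nrow(rg$hits) < 2L) next
    resp <- apply(rg$hits, 1L, function(h) cwt[[h[1L]]][h[2L]])
    best <- which.max(resp)
    s_best <- rg$hits[best, 1L]
    pos <- rg$hits[best, 2L]
    w <- max(2L, round(scale_pts[s_best]))
    lo <- max(1L, pos - w); hi <- min(n, pos + w)
    apex <- lo - 1L + which.max(y[lo:hi])
    y_s <- moving_avg(y, max(3L, round(scale_pts[s_best] / 2)))
    b <- find_bounds(y_s, apex, eps = noise / 2)
    if (b[1L] >= apex || b[2L] <= apex) next
    rt_left <- grid[b[1L]]; rt_right <- grid[b[2L]]
    inwin <- pts$rt >= rt_left & pts$rt <= rt_right
    if (sum(inwin) < 3L) next
    height <- max(pts$intensity[inwin])
    base_lvl <- min(y_s[b])
    snr <- max(0, (y[apex] - base_lvl)) / noise
    if (snr < snr_min) next
    area <- trapz(pts$rt[inwin], pts$intensity[inwin])
    rows[[length(rows) + 1L]] <-
      data.frame(pic_id = pic$pic_id, mz = pic$mz_mean, rt_apex = grid[apex],
                 rt_left = rt_left, rt_right = rt_right, height = height,
                 area = area, snr = snr)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$rt_apex), , drop = FALSE]
  # de-duplicate ridges that landed on the same apex
  out <- out[!duplicated(round(out$rt_apex / dt)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate a retention-time window on a PIC
#'
#' Trapezoidal area over the observed points inside `[rt_left, rt_right]`
#' (no interpolation); height is the maximum observed intensity in the
#' window. A single-point window has zero area by the trapezoid rule.
#'
#' @param pic a `pic` object.
#' @param rt_left,rt_right window bounds in seconds, `rt_left < rt_right`.
#' @return list with elements `area` and `height`.
#' @export
integrate_peak <- function(pic, rt_left, rt_right) {
  stopifnot(inherits(pic, "pic"))
  if (rt_left >= rt_right) stop_user("rt_left must be < rt_right")
  pts <- pic$points
  inwin <- pts$rt >= rt_left & pts$rt <= rt_right
  if (!any(inwin)) stop_user("no observed points in [", rt_left, ", ",
                             rt_right, "]")
  list(area = trapz(pts$rt[inwin], pts$intensity[inwin]),
       height = max(pts$intensity[inwin]))
}

#' Detect peaks on every PIC of a sample
#'
#' @param pics a `pic_list` from [extract_pics].
#' @param scales,snr_min passed to [detect_peaks].
#' @return data.frame of all detected peaks with a `sample_id` column.
#' @export
detect_peaks_all <- function(pics, scales = NULL, snr_min = 3) {
  res <- lapply(pics, detect_peaks, scales = scales, snr_min = snr_min)
  res <- res[vapply(res, nrow, 0L) > 0L]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(pic_id = integer(0), mz = numeric(0), rt_apex = numeric(0),
               rt_left = numeric(0), rt_right = numeric(0),
               height = numeric(0), area = numeric(0), snr = numeric(0))
  cbind(sample_id = rep(attr(pics, "sample_id") %||% NA_character_,
                        nrow(out)), out)
}
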