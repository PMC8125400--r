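# Synthetic centroided LC-MS runs and labeled cohorts with full ground
# truth. Elution profiles are Gaussian (no tailing), m/z values carry
# ppm-scale jitter per point, isotope envelopes ride 1.00336/z above the
# monoisotopic trace, and uniform-random noise points arrive at a Poisson
# rate per scan with exponentially distributed intensities. The defaults
# mirror a short high-resolution gradient: 0.5 s scans over 600 s,
# m/z 100-1000.

#' Draw a set of planted metabolite features
#'
#' @param n number of features.
#' @param mz_range,rt_range m/z (Th) and apex RT (s) ranges to draw from
#'   uniformly. RT range keeps a margin inside the acquisition window.
#' @param sigma_range chromatographic peak width (s, Gaussian sigma).
#' @param height_range apex intensity range (counts, log-uniform).
#' @param isotopes plant M+1/M+2 companion traces with realistic relative
#'   intensities (default TRUE).
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @return data.frame with one row per feature: `feature_id`, `mz`,
#'   `rt_apex`, `sigma_rt`, `height`, `iso1`, `iso2`, `iso3`, `charge`.
#' @export
planted_features <- function(n = 50, mz_range = c(100, 1000),
                             rt_range = c(60, 540),
                             sigma_range = c(3, 8),
                             height_range = c(1e4, 1e6),
                             isotopes = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    feature_id = seq_len(n),
    mz = runif(n, mz_range[1], mz_range[2]),
    rt_apex = runif(n, rt_range[1], rt_range[2]),
    sigma_rt = runif(n, sigma_range[1], sigma_range[2]),
    height = exp(runif(n, log(height_range[1]), log(height_range[2]))),
    iso1 = if (isotopes) runif(n, 0.1, 0.3) else 0,
    iso2 = if (isotopes) runif(n, 0.01, 0.08) else 0,
    iso3 = 0,
    charge = 1L)
}

#' Simulate one centroided run from planted features
#'
#' Each feature (and each isotope companion with non-zero relative
#' intensity) contributes a Gaussian elution profile sampled at the scan
#' grid wherever the intensity reaches 1 count; every point's m/z is
#' jittered with `mz_jitter_ppm` ppm (1 sd) around the trace m/z. Noise
#' points are added per scan at a Poisson rate with uniform m/z and
#' exponential intensity.
#'
#' @param features data.frame as from [planted_features].
#' @param rt_grid scan times in seconds (default 0.5 s over 600 s).
#' @param mz_jitter_ppm per-point m/z jitter, ppm (1 sd).
#' @param noise_per_scan expected noise points per scan.
#' @param noise_mean mean noise intensity; default 5% of the median
#'   planted height.
#' @param mz_range m/z window for noise points.
#' @param sample_id sample identifier.
#' @param seed RNG seed; `NULL` continues the current stream (used when a
#'   cohort generator owns the seed).
#' @return list with `run` (an [ms_run]) and `truth` (data.frame: one row
#'   per planted trace with `feature_id`, `iso`, `mz`, `rt_apex`,
#'   `sigma_rt`, `height`, `area` = height * sigma * sqrt(2*pi), and
#'   `n_scans` actually sampled).
#' @export
simulate_run <- function(features, rt_grid = seq(0, 600, by = 0.5),
                         mz_jitter_ppm = 5, noise_per_scan = 10,
                         noise_mean = NULL, mz_range = c(100, 1000),
                         sample_id = "sample", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  iso_delta <- 1.00336
  if (is.null(noise_mean))
    noise_mean <- 0.05 * median(features$height)
  scan <- integer(0); mzv <- numeric(0); inten <- numeric(0)
  truth <- list()
  iso_cols <- c("iso1", "iso2", "iso3")
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    rels <- c(1, as.numeric(f[iso_cols]))
    for (k in 0:3) {
      rel <- rels[k + 1L]
      if (rel <= 0) next
      trace_mz <- f$mz + k * iso_delta / f$charge
      mu <- f$height * rel *
        exp(-(rt_grid - f$rt_apex)^2 / (2 * f$sigma_rt^2))
      on_scan <- which(mu >= 1)
      if (length(on_scan)) {
        scan <- c(scan, on_scan)
        mzv <- c(mzv, trace_mz *
                   (1 + rnorm(length(on_scan)) * mz_jitter_ppm * 1e-6))
        inten <- c(inten, mu[on_scan])
      }
      truth[[length(truth) + 1L]] <- data.frame(
        feature_id = f$feature_id, iso = k, mz = trace_mz,
        rt_apex = f$rt_apex, sigma_rt = f$sigma_rt,
        height = f$height * rel,
        area = f$height * rel * f$sigma_rt * sqrt(2 * pi),
        n_scans = length(on_scan))
    }
  }
  n_noise <- rpois(length(rt_grid), noise_per_scan)
  if (sum(n_noise)) {
    scan <- c(scan, rep(seq_along(rt_grid), n_noise))
    mzv <- c(mzv, runif(sum(n_noise), mz_range[1], mz_range[2]))
    inten <- c(inten, rexp(sum(n_noise), rate = 1 / noise_mean))
  }
  o <- order(scan, mzv)
  scan <- scan[o]; mzv <- mzv[o]; inten <- inten[o]
  sf <- factor(scan, levels = seq_along(rt_grid))
  spectra <- Map(function(m, y) list(mz = m, intensity = y),
                 split(mzv, sf), split(inten, sf))
  names(spectra) <- NULL
  run <- ms_run(sample_id, rt_grid, spectra,
                metadata = list(synthetic = TRUE))
  list(run = run, truth = do.call(rbind, truth))
}

#' Specification of a synthetic two-or-more-class cohort
#'
#' Defaults emulate a small discovery cohort: balanced classes, log-normal
#' between-sample intensity variation (CV 0.3), 5 ppm m/z and 3 s RT
#' jitter between samples, and a handful of discriminant features at
#' 4-fold change -- the sort of effect a marker-screening study targets.
#'
#' @param n_classes,n_per_class cohort design.
#' @param n_features planted features per sample.
#' @param n_discriminant number of marker features (`<= n_features`).
#' @param fold_change multiplicative class effect on marker features
#'   (1 = null cohort).
#' @param mz_jitter_ppm per-point m/z jitter (ppm, 1 sd).
#' @param rt_jitter_s per-sample RT jitter of each apex (s, 1 sd).
#' @param noise_points_per_scan Poisson noise rate per scan.
#' @param intensity_cv between-sample coefficient of variation of feature
#'   intensities (log-normal).
#' @param rt_grid scan grid in seconds.
#' @param mz_range m/z window.
#' @param seed RNG seed.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_classes = 2, n_per_class = 6, n_features = 50,
                        n_discriminant = 5, fold_change = 4,
                        mz_jitter_ppm = 5, rt_jitter_s = 3,
                        noise_points_per_scan = 10, intensity_cv = 0.3,
                        rt_grid = seq(0, 600, by = 0.5),
                        mz_range = c(100, 1000), seed = 1) {
  if (n_discriminant > n_features)
    stop_user("n_discriminant must be <= n_features")
  if (any(c(mz_jitter_ppm, rt_jitter_s, noise_points_per_scan,
            intensity_cv) < 0))
    stop_user("rates and jitters must be >= 0")
  structure(list(n_classes = n_classes, n_per_class = n_per_class,
                 n_features = n_features, n_discriminant = n_discriminant,
                 fold_change = fold_change, mz_jitter_ppm = mz_jitter_ppm,
                 rt_jitter_s = rt_jitter_s,
                 noise_points_per_scan = noise_points_per_scan,
                 intensity_cv = intensity_cv, rt_grid = rt_grid,
                 mz_range = mz_range, seed = seed),
            class = "cohort_spec")
}

cohort_truth_features <- function(spec) {
  feats <- planted_features(spec$n_features, mz_range = spec$mz_range,
                            rt_range = c(0.1, 0.9) *
                              max(spec$rt_grid))
  markers <- sort(sample.int(spec$n_features, spec$n_discriminant))
  up_in <- if (spec$n_classes >= 2L) seq(2L, spec$n_classes) else 1L
  target <- rep_len(up_in, length(markers))
  feats$marker <- feats$feature_id %in% markers
  feats$target_class <- NA_integer_
  feats$target_class[markers] <- target
  feats
}

#' Simulate a labeled cohort of raw runs
#'
#' One base feature set is drawn once; every sample re-draws feature
#' heights log-normally around the class mean (marker features scaled by
#' `fold_change` in their target class), jitters each apex RT, and renders
#' a centroided run via [simulate_run]. All randomness flows from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @return list with `runs` (named list of [ms_run]), `labels` (named
#'   character), and `truth` (list: `features` with marker flags,
#'   `samples` with per-sample realized traces).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  feats <- cohort_truth_features(spec)
  sdlog <- sqrt(log(1 + spec$intensity_cv^2))
  runs <- list(); labels <- character(0); per_sample <- list()
  for (cl in seq_len(spec$n_classes)) {
    for (rep_i in seq_len(spec$n_per_class)) {
      sid <- sprintf("class%d_%02d", cl, rep_i)
      f <- feats
      fc <- ifelse(f$marker & !is.na(f$target_class) &
                     f$target_class == cl, spec$fold_change, 1)
      f$height <- f$height * fc * exp(rnorm(nrow(f)) * sdlog)
      f$rt_apex <- f$rt_apex + rnorm(nrow(f)) * spec$rt_jitter_s
      sim <- simulate_run(f, rt_grid = spec$rt_grid,
                          mz_jitter_ppm = spec$mz_jitter_ppm,
                          noise_per_scan = spec$noise_points_per_scan,
                          mz_range = spec$mz_range, sample_id = sid,
                          seed = NULL)
      runs[[sid]] <- sim$run
      labels[sid] <- paste0("class", cl)
      per_sample[[sid]] <- cbind(sample_id = sid, sim$truth)
    }
  }
  list(runs = runs, labels = labels,
       truth = list(features = feats,
                    samples = do.call(rbind, per_sample)))
}

#' Simulate a feature table directly (no chromatography)
#'
#' Fast path for modeling studies: intensities are drawn from the same
#' log-normal class model as [simulate_cohort] but written straight into a
#' samples x features table, so marker columns have a class-mean ratio of
#' `fold_change` and non-marker columns a ratio of 1 in expectation.
#'
#' @param spec a [cohort_spec].
#' @return list with `table` (an unnormalized [peak_table] carrying
#'   labels), `labels`, and `truth` (marker feature ids and target
#'   classes).
#' @export
simulate_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  feats <- cohort_truth_features(spec)
  n <- spec$n_classes * spec$n_per_class
  sdlog <- sqrt(log(1 + spec$intensity_cv^2))
  sample_ids <- character(n); labels <- character(n)
  mat <- matrix(0, n, spec$n_features)
  r <- 0L
  for (cl in seq_len(spec$n_classes)) {
    fc <- ifelse(feats$marker & !is.na(feats$target_class) &
                   feats$target_class == cl, spec$fold_change, 1)
    for (rep_i in seq_len(spec$n_per_class)) {
      r <- r + 1L
      sample_ids[r] <- sprintf("class%d_%02d", cl, rep_i)
      labels[r] <- paste0("class", cl)
      mat[r, ] <- feats$height * fc * exp(rnorm(spec$n_features) * sdlog)
    }
  }
  rownames(mat) <- sample_ids
  labels <- setNames(labels, sample_ids)
  tbl <- peak_table(mat,
                    data.frame(group_id = feats$feature_id,
                               mz = feats$mz, rt = feats$rt_apex),
                    labels = labels, normalized = FALSE)
  list(table = tbl, labels = labels,
       truth = list(markers = which(feats$marker),
                    target_class = feats$target_class[feats$marker],
                    features = feats))
}
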