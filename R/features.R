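# Cross-sample feature construction: retention-time shift correction,
# greedy density-based grouping, isotope/adduct annotation, missing-value
# filling and normalization of the resulting peak table.

#' Correct per-sample retention-time shifts against a reference
#'
#' For every sample, peaks are matched to the reference sample's peaks
#' within twice the grouping tolerances; only unambiguous matches (unique
#' in both directions) are kept, and the median RT offset of those matches
#' is subtracted from all of the sample's peaks. A simple global-shift
#' stand-in for full retention-time alignment.
#'
#' @param peaks_by_sample named list of per-sample peak data.frames (as
#'   from [detect_peaks_all], columns incl. `mz`, `rt_apex`).
#' @param reference sample id to align against.
#' @param mz_tol_ppm,rt_tol_s matching tolerances (halved relative to the
#'   doubled matching window used for candidate pairs).
#' @return list with `peaks` (shifted copies) and `shifts` (named numeric,
#'   seconds subtracted per sample).
#' @export
rt_shift_correct <- function(peaks_by_sample, reference,
                             mz_tol_ppm = 10, rt_tol_s = 10) {
  if (length(peaks_by_sample) < 2L)
    stop_user("need at least 2 samples for RT shift correction")
  if (!reference %in% names(peaks_by_sample))
    stop_user("reference sample '", reference, "' not found")
  ref <- peaks_by_sample[[reference]]
  shifts <- setNames(numeric(length(peaks_by_sample)),
                     names(peaks_by_sample))
  out <- peaks_by_sample
  for (sid in names(peaks_by_sample)) {
    if (sid == reference) next
    pk <- peaks_by_sample[[sid]]
    if (!nrow(pk) || !nrow(ref)) {
      warning("no peaks to match for sample '", sid, "'; shift set to 0")
      next
    }
    # candidate matches within doubled tolerances
    cand_ref <- lapply(seq_len(nrow(pk)), function(i) {
      which(abs(ref$mz - pk$mz[i]) <= 2 * mz_tol_ppm * 1e-6 * pk$mz[i] &
              abs(ref$rt_apex - pk$rt_apex[i]) <= 2 * rt_tol_s)
    })
    uniq <- which(vapply(cand_ref, length, 0L) == 1L)
    refidx <- vapply(cand_ref[uniq], `[[`, 0L, 1L)
    keep <- !(duplicated(refidx) | duplicated(refidx, fromLast = TRUE))
    if (!any(keep)) {
      warning("no unambiguous matches for sample '", sid,
              "'; shift set to 0")
      next
    }
    shift <- median(pk$rt_apex[uniq[keep]] - ref$rt_apex[refidx[keep]])
    shifts[[sid]] <- shift
    for (col in intersect(c("rt_apex", "rt_left", "rt_right"), names(pk)))
      pk[[col]] <- pk[[col]] - shift
    out[[sid]] <- pk
  }
  list(peaks = out, shifts = shifts)
}

#' Group peaks across samples into features
#'
#' Greedy density-based grouping: the unassigned peak with the highest area
#' seeds a new group; all unassigned peaks within `mz_tol_ppm` and
#' `rt_tol_s` of the seed join it, keeping at most one peak per sample
#' (highest area wins); a second absorption pass re-collects unassigned
#' peaks around the group's consensus (median) position, so a seed at the
#' retention-time edge of its feature does not split it in two; this
#' repeats until every peak is assigned. Groups
#' detected in fewer than `min_frac` of the samples of every class are
#' dropped (with `labels = NULL` all samples count as one class). The
#' result is a partition: every peak belongs to exactly one kept or
#' dropped group.
#'
#' @param peaks_by_sample named list of per-sample peak data.frames.
#' @param mz_tol_ppm,rt_tol_s grouping tolerances.
#' @param min_frac minimum detection fraction within at least one class.
#' @param labels optional named vector mapping sample id to class label.
#' @return list of feature groups (class `feature_groups`); each group is a
#'   list with `group_id`, `mz_consensus`, `rt_consensus`, `members` (named
#'   list sample id -> peak row), `isotope_tag`, `adduct_tag`.
#' @export
group_across_samples <- function(peaks_by_sample, mz_tol_ppm = 10,
                                 rt_tol_s = 10, min_frac = 0.5,
                                 labels = NULL) {
  nonempty <- vapply(peaks_by_sample, nrow, 0L) > 0L
  if (!any(nonempty)) stop_user("no peaks in any sample")
  pool <- do.call(rbind, lapply(names(peaks_by_sample)[nonempty],
                                function(sid)
                                  cbind(sample_id = sid,
                                        peaks_by_sample[[sid]])))
  rownames(pool) <- NULL
  n <- nrow(pool)
  assigned <- rep(FALSE, n)
  seed_order <- order(-pool$area)
  groups <- list()
  for (s in seed_order) {
    if (assigned[s]) next
    cand <- which(!assigned &
                    abs(pool$mz - pool$mz[s]) <= mz_tol_ppm * 1e-6 * pool$mz[s] &
                    abs(pool$rt_apex - pool$rt_apex[s]) <= rt_tol_s)
    # one peak per sample: highest area wins
    o <- cand[order(pool$sample_id[cand], -pool$area[cand])]
    o <- o[!duplicated(pool$sample_id[o])]
    assigned[o] <- TRUE
    assigned[cand] <- TRUE   # losers of the per-sample contest are consumed too
    # absorption pass: a seed sitting at the RT edge of its feature can
    # miss members on the far edge; re-collect unassigned peaks around the
    # group consensus so one planted feature forms one group
    mzc <- median(pool$mz[o]); rtc <- median(pool$rt_apex[o])
    extra <- which(!assigned &
                     !(pool$sample_id %in% pool$sample_id[o]) &
                     abs(pool$mz - mzc) <= mz_tol_ppm * 1e-6 * mzc &
                     abs(pool$rt_apex - rtc) <= rt_tol_s)
    if (length(extra)) {
      e <- extra[order(pool$sample_id[extra], -pool$area[extra])]
      e <- e[!duplicated(pool$sample_id[e])]
      assigned[e] <- TRUE
      assigned[extra] <- TRUE
      o <- c(o, e)
    }
    members <- lapply(o, function(i) pool[i, -1L, drop = FALSE])
    names(members) <- pool$sample_id[o]
    groups[[length(groups) + 1L]] <-
      list(group_id = NA_integer_,
           mz_consensus = median(pool$mz[o]),
           rt_consensus = median(pool$rt_apex[o]),
           members = members, isotope_tag = NULL, adduct_tag = NULL)
  }
  # min_frac filter per class
  all_samples <- names(peaks_by_sample)
  if (is.null(labels)) labels <- setNames(rep("all", length(all_samples)),
                                          all_samples)
  class_sizes <- table(labels[all_samples])
  keep <- vapply(groups, function(g) {
    present <- table(factor(labels[names(g$members)],
                            levels = names(class_sizes)))
    any(present / as.numeric(class_sizes) >= min_frac)
  }, TRUE)
  groups <- groups[keep]
  o <- order(vapply(groups, `[[`, 0, "mz_consensus"),
             vapply(groups, `[[`, 0, "rt_consensus"))
  groups <- groups[o]
  for (i in seq_along(groups)) groups[[i]]$group_id <- i
  structure(groups, class = "feature_groups")
}

#' @export
print.feature_groups <- function(x, ...) {
  cat("<feature_groups> ", length(x), " features; ",
      sum(!vapply(x, function(g) is.null(g$isotope_tag), TRUE)),
      " isotope-tagged, ",
      sum(!vapply(x, function(g) is.null(g$adduct_tag), TRUE)),
      " adduct-tagged\n", sep = "")
  invisible(x)
}

group_mean_intensity <- function(g)
  mean(vapply(g$members, function(m) m$area, 0))

#' Tag isotope companion features
#'
#' Candidate parents are visited in order of decreasing mean intensity. A
#' group lying at `mz_consensus + k * delta_mz / z` (k = 1..3, within the
#' ppm tolerance), co-eluting within `rt_tol_s`, and less intense than the
#' parent is tagged as that parent's k-th isotope at charge z. A group
#' keeps at most one isotope tag (first parent wins). Tags are annotations
#' only; tagged features stay in the table.
#'
#' @param groups a `feature_groups` object.
#' @param delta_mz isotope spacing in Da (C13-C12 mass difference).
#' @param charges charge states to consider.
#' @param mz_tol_ppm,rt_tol_s matching tolerances.
#' @return the annotated `feature_groups`.
#' @export
annotate_isotopes <- function(groups, delta_mz = 1.00336, charges = c(1, 2),
                              mz_tol_ppm = 10, rt_tol_s = 10) {
  if (!length(groups)) return(groups)
  mz <- vapply(groups, `[[`, 0, "mz_consensus")
  rt <- vapply(groups, `[[`, 0, "rt_consensus")
  inten <- vapply(groups, group_mean_intensity, 0)
  for (p in order(-inten)) {
    for (z in charges) {
      for (k in 1:3) {
        target <- mz[p] + k * delta_mz / z
        hits <- which(abs(mz - target) <= mz_tol_ppm * 1e-6 * target &
                        abs(rt - rt[p]) <= rt_tol_s &
                        inten < inten[p])
        for (h in hits) {
          if (h == p || !is.null(groups[[h]]$isotope_tag)) next
          groups[[h]]$isotope_tag <-
            list(parent = groups[[p]]$group_id, isotope = k, charge = z)
        }
      }
    }
  }
  groups
}

#' Default positive-mode adduct table
#'
#' @return data.frame with columns `name`, `shift` (Da), `charge`.
#' @export
default_adducts <- function() {
  data.frame(name = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+K]+"),
             shift = c(1.007276, 18.033823, 22.989218, 38.963158),
             charge = 1L)
}

#' Tag adduct pairs sharing a neutral mass
#'
#' Co-eluting group pairs whose m/z difference matches the difference of
#' two adduct shifts (within the ppm tolerance) are tagged with the shared
#' inferred neutral mass. A group keeps its first tag.
#'
#' @param groups a `feature_groups` object.
#' @param adduct_table data.frame like [default_adducts()].
#' @param mz_tol_ppm,rt_tol_s matching tolerances.
#' @return the annotated `feature_groups`.
#' @export
annotate_adducts <- function(groups, adduct_table = default_adducts(),
                             mz_tol_ppm = 10, rt_tol_s = 10) {
  if (!length(groups) || !nrow(adduct_table)) return(groups)
  mz <- vapply(groups, `[[`, 0, "mz_consensus")
  rt <- vapply(groups, `[[`, 0, "rt_consensus")
  ng <- length(groups)
  na <- nrow(adduct_table)
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      if (i == j || abs(rt[i] - rt[j]) > rt_tol_s) next
      for (a in seq_len(na)) {
        for (b in seq_len(na)) {
          if (a == b) next
          dshift <- adduct_table$shift[a] - adduct_table$shift[b]
          if (abs((mz[i] - mz[j]) - dshift) <= mz_tol_ppm * 1e-6 * mz[i]) {
            neutral <- ((mz[i] - adduct_table$shift[a]) +
                          (mz[j] - adduct_table$shift[b])) / 2
            if (is.null(groups[[i]]$adduct_tag))
              groups[[i]]$adduct_tag <-
                list(name = adduct_table$name[a], neutral_mass = neutral)
            if (is.null(groups[[j]]$adduct_tag))
              groups[[j]]$adduct_tag <-
                list(name = adduct_table$name[b], neutral_mass = neutral)
          }
        }
      }
    }
  }
  groups
}

#' Construct a peak table
#'
#' @param matrix samples x features intensity matrix (row names = samples).
#' @param features data.frame with `group_id`, `mz`, `rt` (one row per
#'   column of `matrix`).
#' @param labels optional named vector sample id -> class label.
#' @param normalized logical flag.
#' @return object of class `peak_table`.
#' @export
peak_table <- function(matrix, features, labels = NULL, normalized = FALSE) {
  if (nrow(features) != ncol(matrix))
    stop_user("feature metadata rows must match matrix columns")
  if (is.null(rownames(matrix))) stop_user("matrix needs sample row names")
  structure(list(sample_ids = rownames(matrix), features = features,
                 matrix = matrix, labels = labels, normalized = normalized),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " features", if (x$normalized) " (normalized)", "\n", sep = "")
  if (!is.null(x$labels))
    cat("  classes:", paste(names(table(x$labels)), table(x$labels),
                            sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$matrix)

#' Fill missing table entries from raw data
#'
#' Builds the samples x features area matrix from the grouped peaks and
#' fills every missing (sample, feature) entry by trapezoid-integrating the
#' sample's raw points inside `mz_consensus` +/- the PIC ppm tolerance and
#' `rt_consensus` +/- `rt_tol_s` (keeping the most intense point per scan).
#' Entries with fewer than two raw points in the window -- no integrable
#' signal -- fall back to half the group's minimum observed area, so the
#' returned table has no missing and no all-zero entries. Detected entries
#' are never altered.
#'
#' @param groups a `feature_groups` object.
#' @param runs named list of [ms_run] objects covering every sample.
#' @param params a [pic_params] (its `mz_tol_ppm` defines the m/z window).
#' @param rt_tol_s RT half-window for re-integration, seconds.
#' @param labels optional named class labels stored in the table.
#' @return an unnormalized [peak_table].
#' @export
fill_missing <- function(groups, runs, params = pic_params(),
                         rt_tol_s = 15, labels = NULL) {
  sample_ids <- names(runs)
  need <- unique(unlist(lapply(groups, function(g) names(g$members))))
  missing_runs <- setdiff(need, sample_ids)
  if (length(missing_runs))
    stop_user("raw run unavailable for sample(s): ",
              paste(missing_runs, collapse = ", "))
  ng <- length(groups)
  mat <- matrix(NA_real_, nrow = length(sample_ids), ncol = ng,
                dimnames = list(sample_ids, NULL))
  for (g in seq_len(ng))
    for (sid in names(groups[[g]]$members))
      mat[sid, g] <- groups[[g]]$members[[sid]]$area
  pts_cache <- lapply(runs, to_points)
  tol <- params$mz_tol_ppm * 1e-6
  for (g in seq_len(ng)) {
    mzc <- groups[[g]]$mz_consensus
    rtc <- groups[[g]]$rt_consensus
    obs_min <- min(mat[, g], na.rm = TRUE)
    for (sid in sample_ids[is.na(mat[, g])]) {
      pts <- pts_cache[[sid]]
      inwin <- abs(pts$mz - mzc) <= tol * mzc &
        abs(pts$rt - rtc) <= rt_tol_s
      sub <- pts[inwin, , drop = FALSE]
      if (nrow(sub) >= 2L) {
        sub <- sub[order(sub$scan_index, -sub$intensity), , drop = FALSE]
        sub <- sub[!duplicated(sub$scan_index), , drop = FALSE]
        area <- if (nrow(sub) >= 2L) trapz(sub$rt, sub$intensity) else 0
        mat[sid, g] <- if (area > 0) area else obs_min / 2
      } else {
        mat[sid, g] <- obs_min / 2
      }
    }
  }
  feats <- data.frame(
    group_id = vapply(groups, `[[`, 0L, "group_id"),
    mz = vapply(groups, `[[`, 0, "mz_consensus"),
    rt = vapply(groups, `[[`, 0, "rt_consensus"),
    isotope = vapply(groups, function(g)
      if (is.null(g$isotope_tag)) "" else
        sprintf("M+%d[z=%d] of %d", g$isotope_tag$isotope,
                g$isotope_tag$charge, g$isotope_tag$parent), ""),
    adduct = vapply(groups, function(g)
      if (is.null(g$adduct_tag)) "" else g$adduct_tag$name, ""))
  peak_table(mat, feats, labels = labels, normalized = FALSE)
}

#' Autoscale a peak table (zero mean, unit variance per feature)
#'
#' Column means and standard deviations are computed on the `fit_on`
#' samples only and applied to all rows, so statistics fitted on a training
#' split carry to the test split without leakage. Zero-variance features
#' are centered but scaled by 1 and flagged.
#'
#' @param table a [peak_table].
#' @param fit_on sample ids to fit the statistics on (default: all).
#' @return the normalized [peak_table]; attributes `center`, `scale` and
#'   `constant_features` record the fit.
#' @export
normalize_table <- function(table, fit_on = NULL) {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(fit_on)) fit_on <- table$sample_ids
  if (!length(fit_on)) stop_user("'fit_on' must name at least one sample")
  if (!all(fit_on %in% table$sample_ids))
    stop_user("'fit_on' contains unknown sample ids")
  sub <- table$matrix[fit_on, , drop = FALSE]
  ctr <- colMeans(sub)
  scl <- apply(sub, 2L, sd)
  if (nrow(sub) == 1L) scl[] <- NA_real_
  constant <- is.na(scl) | scl == 0
  scl[constant] <- 1
  out <- sweep(sweep(table$matrix, 2L, ctr, "-"), 2L, scl, "/")
  res <- peak_table(out, table$features, labels = table$labels,
                    normalized = TRUE)
  attr(res, "center") <- ctr
  attr(res, "scale") <- scl
  attr(res, "constant_features") <- which(constant)
  res
}

feature_coords <- function(x) {
  if (inherits(x, "peak_table")) x$features else as.data.frame(x)
}

#' Match two feature sets (Venn-style overlap)
#'
#' One-to-one greedy matching: candidate pairs within both tolerances are
#' ranked by the combined normalized distance `|dmz|/tol_mz + |drt|/tol_rt`
#' and accepted in ascending order while both partners are free. The counts
#' partition both lists.
#'
#' @param table_a,table_b [peak_table]s or data.frames with `mz` and `rt`.
#' @param mz_tol_ppm,rt_tol_s matching tolerances.
#' @return list with `n_only_a`, `n_common`, `n_only_b` and `pairs`
#'   (data.frame of matched index pairs and distances).
#' @export
match_feature_sets <- function(table_a, table_b, mz_tol_ppm = 10,
                               rt_tol_s = 10) {
  fa <- feature_coords(table_a)
  fb <- feature_coords(table_b)
  na <- nrow(fa); nb <- nrow(fb)
  cand <- list()
  for (i in seq_len(na)) {
    tol_mz <- mz_tol_ppm * 1e-6 * fa$mz[i]
    j <- which(abs(fb$mz - fa$mz[i]) <= tol_mz &
                 abs(fb$rt - fa$rt[i]) <= rt_tol_s)
    if (length(j))
      cand[[length(cand) + 1L]] <- data.frame(
        a = i, b = j,
        dist = abs(fb$mz[j] - fa$mz[i]) / tol_mz +
          abs(fb$rt[j] - fa$rt[i]) / rt_tol_s)
  }
  pairs <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dist, cand$a, cand$b), , drop = FALSE]
    used_a <- rep(FALSE, na); used_b <- rep(FALSE, nb)
    for (r in seq_len(nrow(cand))) {
      i <- cand$a[r]; j <- cand$b[r]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs <- rbind(pairs, cand[r, , drop = FALSE])
    }
  }
  n_common <- nrow(pairs)
  list(n_only_a = na - n_common, n_common = n_common,
       n_only_b = nb - n_common, pairs = pairs)
}

#' Write / read a peak table as CSV
#'
#' Feature-per-row layout: columns `group_id`, `mz`, `rt`, annotation
#' columns, then one column per sample. Labels go to a companion
#' `<path>.labels.csv` when present.
#'
#' @param table a [peak_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- cbind(table$features, as.data.frame(t(table$matrix)))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(table$labels)) {
    lab <- data.frame(sample_id = names(table$labels),
                      label = unname(table$labels))
    write.csv(lab, paste0(path, ".labels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_peak_table
#' @param normalized flag recorded on the reconstructed table.
#' @export
read_peak_table <- function(path, normalized = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("group_id", "mz", "rt", "isotope", "adduct"),
                         names(df))
  feats <- df[meta_cols]
  mat <- t(as.matrix(df[setdiff(names(df), meta_cols)]))
  labels <- NULL
  labfile <- paste0(path, ".labels.csv")
  if (file.exists(labfile)) {
    lab <- read.csv(labfile)
    labels <- setNames(as.character(lab$label), lab$sample_id)
  }
  peak_table(mat, feats, labels = labels, normalized = normalized)
}
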