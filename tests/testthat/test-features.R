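# cross-sample grouping, RT correction, annotation, filling, normalization

fake_peaks <- function(mz, rt, area = NULL, sample_id = NULL) {
  n <- length(mz)
  data.frame(pic_id = seq_len(n), mz = mz, rt_apex = rt,
             rt_left = rt - 5, rt_right = rt + 5,
             height = (area %||% rep(1e5, n)) / 10,
             area = area %||% rep(1e5, n), snr = rep(50, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical peaks across samples form one group; distant ones never merge", {
  pk <- lapply(1:4, function(i) fake_peaks(c(400.0, 400.04), c(100, 100)))
  names(pk) <- paste0("s", 1:4)
  groups <- group_across_samples(pk, mz_tol_ppm = 10, rt_tol_s = 10)
  expect_length(groups, 2L)   # 100 ppm apart -> never merged at 10 ppm
  expect_true(all(vapply(groups, function(g) length(g$members), 0L) == 4L))
  # partition invariant: every input peak lands in exactly one kept group
  expect_identical(sum(vapply(groups, function(g) length(g$members), 0L)),
                   8L)
})

test_that("grouping tolerates planted jitter and drops rare groups per class", {
  set.seed(6)
  mz0 <- seq(200, 900, length.out = 25)
  rt0 <- seq(60, 500, length.out = 25)
  pk <- lapply(1:10, function(i)
    fake_peaks(mz0 * (1 + rnorm(25) * 5e-6), rt0 + rnorm(25) * 3,
               area = runif(25, 1e4, 1e6)))
  names(pk) <- sprintf("s%02d", 1:10)
  groups <- group_across_samples(pk, mz_tol_ppm = 10, rt_tol_s = 10)
  hits <- match_truth(mz0, rt0,
                      vapply(groups, `[[`, 0, "mz_consensus"),
                      vapply(groups, `[[`, 0, "rt_consensus"),
                      ppm = 10, rt_tol = 10)
  expect_gte(mean(hits == 1L), 0.95)
  # a feature present in 2/10 samples of the single class is dropped at min_frac 0.5
  pk$s01 <- rbind(pk$s01, fake_peaks(777.7, 300))
  pk$s02 <- rbind(pk$s02, fake_peaks(777.7, 300))
  g2 <- group_across_samples(pk, mz_tol_ppm = 10, rt_tol_s = 10,
                             min_frac = 0.5)
  expect_false(any(abs(vapply(g2, `[[`, 0, "mz_consensus") - 777.7) < 0.01))
})

test_that("rt_shift_correct recovers planted drifts to within a second", {
  base <- fake_peaks(seq(150, 850, length.out = 30),
                     seq(50, 550, length.out = 30),
                     area = runif(30, 1e4, 1e6))
  drift <- base; drift$rt_apex <- drift$rt_apex + 5
  still <- base
  res <- rt_shift_correct(list(ref = base, d = drift, s = still), "ref")
  expect_identical(res$shifts[["ref"]], 0)
  expect_lte(abs(res$shifts[["d"]] - 5), 1)
  expect_lte(abs(res$shifts[["s"]]), 1)
  expect_equal(res$peaks$d$rt_apex, base$rt_apex, tolerance = 1e-9)
  expect_warning(
    rt_shift_correct(list(a = base, b = fake_peaks(100.1, 580)), "a"),
    "no unambiguous matches")
})

test_that("isotope annotation tags companions with the right index and charge", {
  mk_group <- function(id, mz, rt, area)
    list(group_id = id, mz_consensus = mz, rt_consensus = rt,
         members = list(s1 = data.frame(area = area)),
         isotope_tag = NULL, adduct_tag = NULL)
  groups <- structure(list(
    mk_group(1L, 400.2000, 100, 1e6),
    mk_group(2L, 400.2000 + 1.00336, 100, 2e5),   # M+1 at 20%
    mk_group(3L, 700.5, 300, 5e5)),                # lone feature
    class = "feature_groups")
  ann <- annotate_isotopes(groups)
  expect_identical(ann[[2]]$isotope_tag,
                   list(parent = 1L, isotope = 1L, charge = 1))
  expect_null(ann[[1]]$isotope_tag)
  expect_null(ann[[3]]$isotope_tag)
  # half-Da spacing is a doubly-charged isotope, never z = 1
  g2 <- structure(list(
    mk_group(1L, 300.1000, 50, 1e6),
    mk_group(2L, 300.1000 + 1.00336 / 2, 50, 3e5)),
    class = "feature_groups")
  ann2 <- annotate_isotopes(g2, charges = c(1, 2))
  expect_identical(ann2[[2]]$isotope_tag$charge, 2)
  expect_identical(ann2[[2]]$isotope_tag$isotope, 1L)
})

test_that("adduct annotation infers one shared neutral mass for co-eluting pairs", {
  M <- 321.1
  mk_group <- function(id, mz, rt)
    list(group_id = id, mz_consensus = mz, rt_consensus = rt,
         members = list(s1 = data.frame(area = 1e5)),
         isotope_tag = NULL, adduct_tag = NULL)
  pair <- structure(list(mk_group(1L, M + 1.007276, 120),
                         mk_group(2L, M + 22.989218, 120)),
                    class = "feature_groups")
  ann <- annotate_adducts(pair)
  expect_identical(ann[[1]]$adduct_tag$name, "[M+H]+")
  expect_identical(ann[[2]]$adduct_tag$name, "[M+Na]+")
  expect_lte(abs(ann[[1]]$adduct_tag$neutral_mass - M) / M, 5e-6)
  expect_identical(ann[[1]]$adduct_tag$neutral_mass,
                   ann[[2]]$adduct_tag$neutral_mass)
  # no co-elution -> no tags; empty adduct table -> no tags
  apart <- structure(list(mk_group(1L, M + 1.007276, 120),
                          mk_group(2L, M + 22.989218, 240)),
                     class = "feature_groups")
  expect_null(annotate_adducts(apart)[[1]]$adduct_tag)
  none <- annotate_adducts(pair, adduct_table = default_adducts()[0, ])
  expect_null(none[[1]]$adduct_tag)
})

test_that("fill_missing keeps detected entries, refills from raw data, and falls back", {
  feat <- data.frame(feature_id = 1:2, mz = c(300.15, 601.3),
                     rt_apex = c(100, 200), sigma_rt = c(4, 5),
                     height = c(2e5, 4e5), iso1 = 0, iso2 = 0, iso3 = 0,
                     charge = 1)
  runs <- list()
  peaks <- list()
  for (sid in c("a", "b")) {
    sim <- simulate_run(feat, rt_grid = seq(0, 300, 0.5),
                        mz_jitter_ppm = 1, noise_per_scan = 0,
                        seed = match(sid, c("a", "b")), sample_id = sid)
    runs[[sid]] <- sim$run
    pics <- extract_pics(sim$run, pic_params(min_apex = 10))
    peaks[[sid]] <- detect_peaks_all(pics)
  }
  groups <- group_across_samples(peaks)
  expect_length(groups, 2L)
  full <- fill_missing(groups, runs, pic_params())
  # nothing was missing: the table holds the detected areas unchanged
  for (g in seq_along(groups))
    for (sid in names(groups[[g]]$members))
      expect_identical(unname(full$matrix[sid, g]),
                       groups[[g]]$members[[sid]]$area)
  # delete one detection: the refill must come from the raw signal
  g1 <- groups
  removed <- g1[[1]]$members[["b"]]$area
  g1[[1]]$members[["b"]] <- NULL
  refilled <- fill_missing(g1, runs, pic_params())
  expect_lte(abs(unname(refilled$matrix["b", 1]) - removed) / removed,
             0.2)
  # a feature with no raw signal at all falls back to half the minimum
  ghost <- g1
  ghost[[2]]$mz_consensus <- 999.9
  ghost[[2]]$members <- ghost[[2]]$members["a"]
  refb <- fill_missing(ghost, runs, pic_params())
  expect_identical(unname(refb$matrix["b", 2]),
                   ghost[[2]]$members[["a"]]$area / 2)
  expect_error(fill_missing(groups, runs["a"], pic_params()),
               "unavailable.*b")
})

test_that("normalization fits on the requested rows and flags constant columns", {
  m <- matrix(c(1, 2, 3, 7, 7, 7), ncol = 2,
              dimnames = list(c("r1", "r2", "r3"), NULL))
  tbl <- peak_table(m, data.frame(group_id = 1:2, mz = c(100, 200),
                                  rt = c(10, 20)))
  z <- normalize_table(tbl)
  expect_equal(z$matrix[, 1], c(r1 = -1, r2 = 0, r3 = 1), tolerance = 1e-6)
  expect_equal(unname(z$matrix[, 1] * sd(1:3) + 2), 1:3)  # invertible
  expect_true(all(z$matrix[, 2] == 0))
  expect_identical(attr(z, "constant_features"), 2L)
  # fit on a subset, applied to all rows
  z2 <- normalize_table(tbl, fit_on = c("r1", "r2"))
  expect_equal(mean(z2$matrix[c("r1", "r2"), 1]), 0, tolerance = 1e-9)
  expect_equal(sd(z2$matrix[c("r1", "r2"), 1]), 1, tolerance = 1e-9)
  expect_gt(z2$matrix["r3", 1], 1)
  expect_error(normalize_table(tbl, fit_on = "nope"), "unknown sample")
})

test_that("feature-set matching partitions both lists", {
  fa <- data.frame(mz = seq(100, 400, by = 20), rt = seq(50, 350, by = 20))
  self <- match_feature_sets(fa, fa)
  expect_identical(self$n_common, nrow(fa))
  expect_identical(self$n_only_a, 0L)
  expect_identical(self$n_only_b, 0L)
  fb <- data.frame(mz = fa$mz + 500, rt = fa$rt)
  disjoint <- match_feature_sets(fa, fb)
  expect_identical(disjoint$n_common, 0L)
  extra <- data.frame(mz = c(fa$mz, seq(500, 590, by = 10)),
                      rt = c(fa$rt, seq(400, 490, by = 10)))
  sup <- match_feature_sets(extra, fa)
  expect_identical(sup$n_common, nrow(fa))
  expect_identical(sup$n_only_a, 10L)
  expect_identical(sup$n_only_b, 0L)
  expect_identical(sup$n_only_a + sup$n_common, nrow(extra))
})
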