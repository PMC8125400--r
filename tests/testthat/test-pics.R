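# pure ion chromatogram extraction: regions, clustering, scan resolution

pts_df <- function(scan, rt, mz, intensity)
  data.frame(scan_index = as.integer(scan), rt = rt, mz = mz,
             intensity = intensity)

test_that("find_regions separates distant traces and keeps single traces whole", {
  # two traces 1 Da apart, coarse width 0.1 -> two regions
  two <- pts_df(c(0:4, 0:4), rep(1:5 / 2, 2),
                c(rep(500.0, 5), rep(501.0, 5)), rep(100, 10))
  regs <- find_regions(two, pic_params(coarse_width = 0.1))
  expect_length(regs, 2L)
  expect_identical(sum(vapply(regs, nrow, 0L)), 10L)
  # one trace straddling a slab boundary stays one region
  one <- pts_df(0:5, 1:6 / 2, 500.0 + c(-2, -1, 0, 1, 2, 3) * 1e-3,
                rep(10, 6))
  expect_length(find_regions(one, pic_params(coarse_width = 0.1)), 1L)
  expect_length(find_regions(one[0, ], pic_params()), 0L)
})

test_that("split_region resolves two ion clouds and stops on pure clusters", {
  set.seed(4)
  n <- 40
  cloud <- pts_df(rep(0:(n - 1), 2), rep(seq_len(n) / 2, 2),
                  c(200.000 * (1 + rnorm(n) * 2e-6),
                    200.050 * (1 + rnorm(n) * 2e-6)),
                  runif(2 * n, 50, 150))
  cl <- split_region(cloud, pic_params(mz_tol_ppm = 10))
  expect_length(cl, 2L)
  # brute-force nearest-centroid check of the assignment
  cents <- sort(vapply(cl, function(r) weighted.mean(r$mz, r$intensity), 0))
  expect_equal(cents, c(200.000, 200.050), tolerance = 1e-5)
  for (r in cl) {
    ctr <- weighted.mean(r$mz, r$intensity)
    other <- setdiff(cents, ctr)[which.min(abs(setdiff(cents, ctr) - ctr))]
    expect_true(all(abs(r$mz - ctr) < abs(r$mz - other)))
  }
  # already-pure region returned unchanged; singleton stays singleton
  pure <- pts_df(0:3, 1:4 / 2, rep(300.0, 4), rep(5, 4))
  expect_identical(split_region(pure, pic_params()), list(pure))
  single <- pts_df(0L, 0.5, 150.0, 9)
  expect_length(split_region(single, pic_params()), 1L)
  expect_error(split_region(pure[0, ], pic_params()), "empty")
})

test_that("resolve_scan_duplicates keeps the strongest point with the documented tie-breaks", {
  none <- pts_df(0:2, 1:3 / 2, rep(400, 3), c(1, 2, 3))
  expect_identical(resolve_scan_duplicates(none), none)
  # max-intensity rule
  dup <- pts_df(c(0, 0, 1), c(0.5, 0.5, 1), c(400.0, 400.001, 400.0),
                c(100, 300, 50))
  kept <- resolve_scan_duplicates(dup)
  expect_identical(kept$intensity[kept$scan_index == 0L], 300)
  # intensity tie -> nearest the weighted mean m/z (values exact in binary)
  skew <- pts_df(c(0, 0, 1), c(0.5, 0.5, 1),
                 c(500.0, 500.5, 500.5), c(200, 200, 600))
  wm <- weighted.mean(skew$mz, skew$intensity)   # pulled toward 500.5
  kept <- resolve_scan_duplicates(skew)
  expect_identical(kept$mz[kept$scan_index == 0L], 500.5)
  expect_gt(abs(500.0 - wm), abs(500.5 - wm))
  # full tie (equidistant) -> lowest m/z
  even <- pts_df(c(0, 0), c(0.5, 0.5), c(500.0, 500.5), c(200, 200))
  expect_identical(resolve_scan_duplicates(even)$mz, 500.0)
})

test_that("extract_pics recovers a clean planted trace completely", {
  feat <- data.frame(feature_id = 1, mz = 350.1, rt_apex = 100,
                     sigma_rt = 5, height = 1e5, iso1 = 0, iso2 = 0,
                     iso3 = 0, charge = 1)
  sim <- simulate_run(feat, rt_grid = seq(0, 200, 0.5), mz_jitter_ppm = 1,
                      noise_per_scan = 0, seed = 3)
  pics <- extract_pics(sim$run, pic_params(min_apex = 10))
  expect_length(pics, 1L)
  expect_identical(nrow(pics[[1]]$points), nrow(to_points(sim$run)))
  expect_equal(pics[[1]]$mz_mean, 350.1, tolerance = 1e-3)
  # min_apex above every planted intensity -> nothing extracted
  expect_length(extract_pics(sim$run, pic_params(min_apex = 1e7)), 0L)
})

test_that("extraction is deterministic and never assigns a point twice", {
  sim <- simulate_run(planted_features(12, seed = 8),
                      rt_grid = seq(0, 300, 0.5), noise_per_scan = 10,
                      seed = 21)
  p1 <- extract_pics(sim$run, pic_params())
  p2 <- extract_pics(sim$run, pic_params())
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  flat <- as.data.frame(p1)
  keys <- paste(flat$scan_index, flat$mz)
  expect_false(any(duplicated(keys)))
  expect_lte(nrow(flat), nrow(to_points(sim$run)))
  # purity invariants over every extracted PIC
  for (p in p1) {
    expect_false(any(duplicated(p$points$scan_index)))
    expect_lte((p$mz_hi - p$mz_lo) / p$mz_mean, 2 * 15e-6)
    expect_true(all(diff(p$points$scan_index) <= 3L))  # max_gap = 2
    expect_gte(nrow(p$points), 5L)                     # min_length
  }
})
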