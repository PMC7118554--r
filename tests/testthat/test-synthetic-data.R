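test_that("same spec and seed reproduce the cohort bit-identically", {
  spec <- small_effect_spec(99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_false(identical(
    a$subjects[[1]]$timeseries,
    generate_cohort(small_effect_spec(100))$subjects[[1]]$timeseries))
})

test_that("spec invariants are enforced with informative errors", {
  expect_error(cohort_spec(n_regions = 1), "n_regions")
  expect_error(cohort_spec(n_regions = 10,
                           effect_edges = data.frame(i = 1L, j = 2L,
                                                     start = 0L, end = 100L,
                                                     delta = 1.2)),
               "baseline \\+ delta")
  expect_error(cohort_spec(n_regions = 10,
                           effect_edges = data.frame(i = 1L, j = 2L,
                                                     start = 50L, end = 300L,
                                                     delta = 0.4)),
               "epoch")
  expect_error(cohort_spec(band = c(0.1, 0.01)), "band")
  # a jointly infeasible correlation target is rejected, naming the edges
  bad <- cohort_spec(n_regions = 3,
                     effect_edges = data.frame(i = c(1L, 1L, 2L),
                                               j = c(2L, 3L, 3L),
                                               start = 0L, end = 200L,
                                               delta = c(0.9, 0.9, -0.9)))
  expect_error(generate_cohort(bad), "not positive definite.*\\(1,2\\)")
})

test_that("planted transient effect is recovered by direct correlation", {
  # one edge, delta 0.5, epoch spanning windows 10-20; oracle = correlation
  # of the generated series inside the epoch windows, averaged over seeds
  diffs <- vapply(1:50, function(s) {
    spec <- cohort_spec(n_patients = 8L, n_controls = 8L, n_regions = 6L,
                        effect_edges = data.frame(i = 1L, j = 2L,
                                                  start = 18L, end = 88L,
                                                  delta = 0.5),
                        seed = 1000 + s)
    cohort <- generate_cohort(spec)
    y <- cohort_labels(cohort)
    sc <- window_scheme(50, 2, 200)
    win <- 10:20
    r <- vapply(cohort$subjects, function(su) {
      b <- enumerate_windows(sc)
      mean(vapply(win, function(w) {
        rows <- (b[w, 1] + 1):b[w, 2]
        cor(su$timeseries[rows, 1], su$timeseries[rows, 2])
      }, numeric(1)))
    }, numeric(1))
    mean(r[y == 1]) - mean(r[y == -1])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.5), 0.1)
})

test_that("disabling the band filter makes epoch correlations exact", {
  spec <- cohort_spec(n_patients = 40L, n_controls = 2L, n_regions = 4L,
                      band = NULL,
                      effect_edges = data.frame(i = 1L, j = 2L, start = 40L,
                                                end = 160L, delta = 0.5),
                      seed = 12)
  cohort <- generate_cohort(spec)
  pat <- cohort_labels(cohort) == 1L
  r <- vapply(cohort$subjects[pat], function(su) {
    cor(su$timeseries[41:160, 1], su$timeseries[41:160, 2])
  }, numeric(1))
  expect_lt(abs(mean(r) - 0.5), 0.05)
})

test_that("with no planted effects group differences vanish as n grows", {
  spec <- cohort_spec(n_patients = 100L, n_controls = 100L, n_regions = 20L,
                      seed = 31)
  cohort <- generate_cohort(spec)
  y <- cohort_labels(cohort)
  fm <- build_features(cohort, "sfc")
  m1 <- colMeans(fm$x[y == 1, ]); m0 <- colMeans(fm$x[y == -1, ])
  v1 <- apply(fm$x[y == 1, ], 2, var); v0 <- apply(fm$x[y == -1, ], 2, var)
  z <- (m1 - m0) / sqrt(v1 / 100 + v0 / 100)
  # per-edge 3-standard-error bound; ~0.3% of edges may exceed it by chance
  expect_gte(mean(abs(z) <= 3), 0.99)
  expect_lt(abs(mean(m1 - m0)), 0.01)
})

test_that("over 90% of signal variance lies inside the configured band", {
  cohort <- generate_cohort(small_effect_spec(17, n_patients = 2L,
                                              n_controls = 2L))
  ts <- cohort$subjects[[1]]$timeseries
  Tn <- nrow(ts); tr <- 2
  freqs <- (seq_len(Tn) - 1) / (Tn * tr)
  folded <- pmin(freqs, 1 / tr - freqs)
  inband <- folded >= 0.01 & folded <= 0.1
  pg <- abs(mvfft(ts))^2
  expect_gt(sum(pg[inband, ]) / sum(pg), 0.9)
})

test_that("covariates and clinical scores follow the cohort model", {
  cohort <- generate_cohort(demo_cohort_spec(n_patients = 43L,
                                             n_controls = 56L, seed = 8))
  y <- cohort_labels(cohort)
  cl <- cohort_clinical(cohort)
  expect_true(all(is.na(cl$hamd[y == -1])))
  expect_true(all(is.na(cl$hama[y == -1])))
  expect_true(all(cl$hamd[y == 1] == round(cl$hamd[y == 1])))
  expect_lt(abs(mean(cl$hamd[y == 1]) - 23.4), 2.5)
  expect_lt(abs(mean(cl$hama[y == 1]) - 18.0), 2.5)
  cov <- cohort_covariates(cohort)
  expect_true(all(cov$gender %in% 0:1))
  expect_gt(mean(cov$education[y == -1]), mean(cov$education[y == 1]))
})

test_that("ground-truth columns map planted epochs to contained windows", {
  cohort <- generate_cohort(demo_cohort_spec(seed = 2))
  fm <- build_features(cohort, "dfc")
  tc <- true_feature_columns(cohort, fm$index, fm$scheme)
  # epoch [40,110) at width 50 / step 2 contains starts 40..60: 11 windows
  expect_equal(sum(tc$i == 1 & tc$j == 2), 11L)
  b <- enumerate_windows(fm$scheme)
  for (k in seq_len(nrow(tc))) {
    ee <- cohort$spec$effect_edges
    ek <- ee[ee$i == tc$i[k] & ee$j == tc$j[k], ]
    expect_gte(b[tc$window[k], 1], ek$start)
    expect_lte(b[tc$window[k], 2], ek$end)
  }
  d <- decode_features(fm$index, tc$column)
  expect_identical(d$window, tc$window)
})

test_that("cohorts round-trip through the plain-text exports", {
  cohort <- generate_cohort(demo_cohort_spec(
    n_patients = 3L, n_controls = 3L, n_regions = 8L, seed = 44))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 6L)
  expect_equal(cohort_labels(back), cohort_labels(cohort))
  expect_equal(back$subjects[[1]]$timeseries,
               cohort$subjects[[1]]$timeseries,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cohort_clinical(back), cohort_clinical(cohort))
  expect_equal(back$ground_truth$effect_edges$delta,
               cohort$ground_truth$effect_edges$delta)
  expect_true(file.exists(file.path(dir, "atlas.tsv")))
})
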