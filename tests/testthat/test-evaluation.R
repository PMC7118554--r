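test_that("AUC equals the probability of correct ordering, ties half", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c(-1L, -1L, 1L, 1L))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 20, 30),
                       rep(c(-1L, 1L), each = 3L))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(1L, -1L), 4L))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1L, 4)), "both classes")
})

test_that("Mann-Whitney AUC equals the trapezoidal ROC area exactly", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    labels <- sample(c(rep(1L, 3), rep(-1L, 3),
                       sample(c(1L, -1L), n - 6, replace = TRUE)))
    scores <- round(rnorm(n), sample(0:2, 1)) # induce ties
    ra <- roc_auc(scores, labels)
    expect_equal(ra$auc, trapezoid_auc(ra$roc), tolerance = 1e-12)
    expect_equal(ra$auc, brute_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(50)
  labels <- sample(c(1L, -1L), 50, replace = TRUE, prob = c(0.4, 0.6))
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<", levels = c(-1, 1)))))
})

test_that("a separable cohort is classified perfectly by CV", {
  set.seed(23)
  n <- 40
  y <- rep(c(1L, -1L), each = n / 2)
  x <- cbind(3 * y + rnorm(n, 0, 0.3), rnorm(n))
  params <- kernel_params(1, 0.5)
  rep10 <- repeated_kfold(x, y, params, k = 5, rounds = 3, seed = 1)
  expect_equal(rep10$accuracy, 1)
  expect_equal(rep10$auc, 1)
  lo <- loocv(x, y, params)
  expect_equal(lo$accuracy, 1)
  expect_equal(lo$auc, 1)
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  set.seed(24)
  n1 <- 14L; n0 <- 26L
  y <- c(rep(1L, n1), rep(-1L, n0))
  x <- cbind(0.8 * y + rnorm(n1 + n0), rnorm(n1 + n0))
  r <- loocv(x, y, kernel_params(1, 0.5))
  expect_equal(r$accuracy, (r$sensitivity * n1 + r$specificity * n0) / (n1 + n0))
  expect_true(all(unlist(r[c("sensitivity", "specificity", "accuracy", "auc")]) >= 0))
  expect_true(all(unlist(r[c("sensitivity", "specificity", "accuracy", "auc")]) <= 1))
})

test_that("metrics are invariant under subject reordering", {
  set.seed(25)
  n <- 30
  y <- rep(c(1L, -1L), each = 15L)
  x <- cbind(y + rnorm(n), rnorm(n))
  params <- kernel_params(1, 0.5)
  perm <- sample(n)
  a <- loocv(x, y, params)
  b <- loocv(x[perm, ], y[perm], params)
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$auc, b$auc)
})

test_that("LOOCV agrees with k-fold at k = n", {
  set.seed(26)
  n <- 12
  y <- rep(c(1L, -1L), each = 6L)
  x <- cbind(1.5 * y + rnorm(n, 0, 0.8), rnorm(n))
  params <- kernel_params(1, 0.5)
  lo <- loocv(x, y, params)
  kf <- repeated_kfold(x, y, params, k = n, rounds = 1, stratified = FALSE,
                       seed = 27)
  expect_equal(kf$accuracy, lo$accuracy)
  expect_equal(kf$auc, lo$auc)
})

test_that("the two-subject degenerate LOOCV is defined and deterministic", {
  x <- matrix(c(1, -1, 0.5, -0.5), 2, 2)
  y <- c(1L, -1L)
  a <- loocv(x, y, kernel_params(1, 1))
  b <- loocv(x, y, kernel_params(1, 1))
  # each left-out subject is scored by a single-class remainder model,
  # which can only predict the opposite class
  expect_equal(a$accuracy, 0)
  expect_identical(a$per_round, b$per_round)
})

test_that("stratification limits and fold warnings behave as declared", {
  y <- rep(c(1L, -1L), c(4L, 20L))
  x <- matrix(rnorm(48), 24, 2)
  expect_error(repeated_kfold(x, y, kernel_params(1, 1), k = 10, rounds = 1,
                              seed = 1),
               "smaller group")
  set.seed(1)
  expect_equal(sort(unique(dfcmdd:::make_folds(y, 4))), 1:4)
  f <- dfcmdd:::make_folds(y, 4)
  expect_true(all(table(f, y)[, "1"] == 1))
})

test_that("hold-out reproduces the 73/26 stratified split shape", {
  cohort <- generate_cohort(demo_cohort_spec(n_patients = 43L,
                                             n_controls = 56L,
                                             n_regions = 10L, seed = 30))
  fm <- build_features(cohort, "dfc")
  y <- cohort_labels(cohort)
  ho <- holdout_protocol(fm$x, y, cohort_covariates(cohort),
                         train_counts = c(patient = 33, control = 40),
                         params = kernel_params(1, 0.01),
                         n_max = 20L, eval_rounds = 2L, seed = 31)
  expect_equal(sum(ho$split), 73L)
  expect_equal(sum(!ho$split), 26L)
  expect_equal(sum(y[!ho$split] == 1L), 10L)
  expect_equal(sum(y[!ho$split] == -1L), 16L)
  expect_s3_class(ho$train_report, "evaluation_report")
  expect_s3_class(ho$test_report, "evaluation_report")
})

test_that("hold-out test AUC tracks train CV AUC on planted-effect cohorts", {
  gaps <- vapply(1:3, function(s) {
    cohort <- generate_cohort(small_effect_spec(400 + s, n_patients = 40L,
                                                n_controls = 40L))
    fm <- build_features(cohort, "dfc")
    ho <- holdout_protocol(fm$x, cohort_labels(cohort),
                           cohort_covariates(cohort),
                           grids = study_grids(), n_max = 20L,
                           eval_rounds = 2L, seed = s)
    abs(ho$test_auc - ho$train_cv_auc)
  }, numeric(1))
  expect_lte(median(gaps), 0.15)
})
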