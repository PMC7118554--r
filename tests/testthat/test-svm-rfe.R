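make_xor_cloud <- function(seed = 1, per_quadrant = 4L, spread = 0.25) {
  set.seed(seed)
  centers <- expand.grid(x = c(-1, 1), y = c(-1, 1))
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(q) {
    cbind(rnorm(per_quadrant, centers$x[q], spread),
          rnorm(per_quadrant, centers$y[q], spread))
  }))
  y <- rep(ifelse(centers$x * centers$y > 0, 1L, -1L), each = per_quadrant)
  list(x = x, y = y)
}

test_that("grid search breaks ties toward the smallest cost then gamma", {
  set.seed(1)
  x <- cbind(c(rnorm(10, 5), rnorm(10, -5)), rnorm(20))
  y <- rep(c(1L, -1L), each = 10L)
  p <- svm_grid_search(x, y, cost_grid = c(4, 1, 16), gamma_grid = c(2, 0.5),
                       k = 5, seed = 2)
  expect_equal(attr(p, "accuracy"), 1)
  expect_equal(p$cost, 1)
  expect_equal(p$gamma, 0.5)
})

test_that("grid search is deterministic under a fixed seed", {
  d <- make_xor_cloud(3, per_quadrant = 6L)
  a <- svm_grid_search(d$x, d$y, c(1, 10), c(0.1, 1), seed = 5)
  b <- svm_grid_search(d$x, d$y, c(1, 10), c(0.1, 1), seed = 5)
  expect_identical(unclass(a)[c("cost", "gamma")],
                   unclass(b)[c("cost", "gamma")])
  expect_identical(attr(a, "table"), attr(b, "table"))
})

test_that("the RBF kernel solves XOR where a linear kernel cannot", {
  d <- make_xor_cloud(7, per_quadrant = 8L)
  p <- svm_grid_search(d$x, d$y, cost_grid = 2^(0:6), gamma_grid = 2^(-2:3),
                       k = 4, seed = 1)
  expect_gt(attr(p, "accuracy"), 0.9)
  # linear-kernel oracle on the same folds stays near chance
  set.seed(1)
  folds <- rep_len(1:4, length(d$y))[sample(length(d$y))]
  lin_acc <- mean(vapply(1:4, function(f) {
    m <- e1071::svm(d$x[folds != f, ], factor(d$y[folds != f]),
                    kernel = "linear", cost = 1, scale = FALSE)
    mean(as.integer(as.character(predict(m, d$x[folds == f, , drop = FALSE])))
         == d$y[folds == f])
  }, numeric(1)))
  expect_lt(lin_acc, 0.7)
  expect_error(svm_grid_search(d$x, rep(1L, length(d$y)), 1, 1), "classes")
  expect_error(svm_grid_search(d$x, d$y, numeric(0), 1), "empty")
})

test_that("kernel elimination criterion matches brute-force kernel sums", {
  set.seed(11)
  x <- matrix(rnorm(10 * 3), 10, 3)
  y <- rep(c(1L, -1L), 5L)
  params <- kernel_params(2, 0.7)
  model <- fit_rbf_svm(x, y, params)
  expect_lt(max(abs(rfe_delta_j(model, 0.7) - brute_delta_j(model, 0.7))),
            1e-10)
})

test_that("duplicated columns tie on dJ and the lower index falls first", {
  set.seed(12)
  base <- matrix(rnorm(20 * 2), 20, 2)
  x <- cbind(base[, 1], base[, 1], base[, 2])
  y <- rep(c(1L, -1L), each = 10L)
  params <- kernel_params(1, 0.5)
  model <- fit_rbf_svm(x, y, params)
  dj <- rfe_delta_j(model, 0.5)
  expect_equal(dj[1], dj[2], tolerance = 1e-10)
  rk <- rfe_rank(x, y, params)
  # column 1 is eliminated before its duplicate column 2
  expect_lt(which(rk$elimination_order == 1L),
            which(rk$elimination_order == 2L))
})

test_that("a perfectly separating feature survives to the final rounds", {
  survived <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 60
    y <- rep(c(1L, -1L), each = n / 2)
    x <- cbind(ifelse(y == 1, 1, -1) + rnorm(n, 0, 0.15),
               matrix(rnorm(n * 49), n, 49))
    rk <- rfe_rank(x, y, kernel_params(1, 1 / 50),
                   one_by_one_below = 100L)
    which(rk$ranking == 1L) <= 2L
  }, logical(1))
  expect_gte(sum(survived), 19L)
})

test_that("rankings are permutations and deterministic", {
  set.seed(14)
  x <- matrix(rnorm(30 * 12), 30, 12)
  y <- rep(c(1L, -1L), 15L)
  params <- kernel_params(1, 0.1)
  rk <- rfe_rank(x, y, params)
  expect_setequal(rk$ranking, 1:12)
  expect_identical(rk$ranking, rev(rk$elimination_order))
  expect_identical(rk$ranking, rfe_rank(x, y, params)$ranking)
  expect_error(rfe_rank(x[, 1, drop = FALSE], y, params), "two features")
})

test_that("subset selection on pure noise stays near chance", {
  set.seed(15)
  x <- matrix(rnorm(80 * 20), 80, 20)
  y <- rep(c(1L, -1L), each = 40L)
  params <- kernel_params(1, 1 / 20)
  # a data-independent ranking isolates the AUC-curve estimator itself;
  # ranking fitted to the same noise would add selection optimism by design
  res <- select_optimal_subset(1:20, x, y, params, n_max = 10, seed = 16)
  expect_lt(abs(mean(res$auc_curve$auc) - 0.5), 0.12)
  expect_lt(max(res$auc_curve$auc), 0.7)
})

test_that("planted informative features are recalled by the optimal subset", {
  recalls <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 60
    y <- rep(c(1L, -1L), each = n / 2)
    x <- cbind(matrix(0.75 * y + rnorm(n * 5), n, 5),
               matrix(rnorm(n * 95), n, 95))
    params <- kernel_params(1, 1 / 100)
    rk <- rfe_rank(x, y, params)
    res <- select_optimal_subset(rk, x, y, params, n_max = 20, seed = s)
    c(recall = mean(1:5 %in% res$optimal_columns),
      n = res$optimal_n)
  }, numeric(2))
  expect_gte(mean(recalls["recall", ]), 0.8)
  expect_lte(median(recalls["n", ]), 15)
})

test_that("subset weights are the rank positions rescaled onto [1, 0]", {
  set.seed(17)
  x <- matrix(rnorm(40 * 8), 40, 8)
  y <- rep(c(1L, -1L), each = 20L)
  params <- kernel_params(1, 0.125)
  res <- select_optimal_subset(rfe_rank(x, y, params), x, y, params,
                               n_max = 8, seed = 18)
  w <- unname(res$weights)
  expect_equal(w[1], 1)
  if (res$optimal_n >= 2L) {
    expect_equal(w[res$optimal_n], 0)
    expect_equal(w, seq(1, 0, length.out = res$optimal_n))
  }
  # the printed pattern for a 3-feature subset
  expect_equal(seq(1, 0, length.out = 3), c(1, 0.5, 0))
})
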