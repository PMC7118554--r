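# RBF-kernel SVM plumbing shared by grid search, RFE and evaluation.
# Labels are integers in {+1 patient, -1 control} throughout; decision
# scores are oriented so larger values favour the patient class.

fit_rbf_svm <- function(x, y, params) {
  e1071::svm(as.matrix(x), factor(y, levels = c(-1L, 1L)),
             type = "C-classification", kernel = "radial",
             cost = params$cost, gamma = params$gamma, scale = FALSE)
}

svm_decision_scores <- function(model, x) {
  pred <- stats::predict(model, as.matrix(x), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  s <- dv[, 1L]
  # column name "A/B": positive decision value favours class A
  if (startsWith(colnames(dv)[1L], "-1")) s <- -s
  unname(s)
}

svm_predict_labels <- function(model, x) {
  as.integer(as.character(stats::predict(model, as.matrix(x))))
}

#' Kernel parameters
#'
#' @param cost SVM cost C (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @return a `kernel_params` list.
#' @export
kernel_params <- function(cost, gamma) {
  if (cost <= 0 || gamma <= 0) stop("cost and gamma must be > 0")
  structure(list(cost = cost, gamma = gamma), class = "kernel_params")
}

#' Default (-c, -g) grids
#'
#' The conventional libsvm-style power-of-two grids: C over 2^-5 ... 2^15,
#' gamma over 2^-15 ... 2^3. `coarse = TRUE` thins both by taking every
#' second exponent, which is what the desk-scale studies use.
#'
#' @param coarse thin the grids for speed.
#' @return list(cost=, gamma=).
#' @export
default_svm_grids <- function(coarse = FALSE) {
  by <- if (coarse) 2L else 1L
  list(cost = 2^seq(-5L, 15L, by = by), gamma = 2^seq(-15L, 3L, by = by))
}

# fold assignment; stratified keeps the class ratio in every fold.
# Uses the current RNG state (callers seed).
make_folds <- function(y, k, stratified = TRUE) {
  folds <- integer(length(y))
  if (stratified) {
    for (g in unique(y)) {
      w <- which(y == g)
      if (k > length(w)) {
        stop(sprintf("k = %d exceeds the smaller group size (%d)",
                     k, length(w)))
      }
      folds[w] <- sample(rep_len(seq_len(k), length(w)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), length(y)))
  }
  folds
}

# held-out decision scores and predicted labels for every subject under
# k-fold CV with the given fixed parameters
cv_scores <- function(x, y, params, k = 5L, stratified = TRUE) {
  x <- as.matrix(x)
  folds <- make_folds(y, k, stratified)
  scores <- numeric(length(y)); pred <- integer(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    model <- fit_rbf_svm(x[tr, , drop = FALSE], y[tr], params)
    scores[te] <- svm_decision_scores(model, x[te, , drop = FALSE])
    pred[te] <- svm_predict_labels(model, x[te, , drop = FALSE])
  }
  list(scores = scores, predicted = pred, folds = folds)
}

#' Grid search for (C, gamma)
#'
#' Selects the RBF-kernel cost and gamma maximizing mean k-fold CV accuracy.
#' Ties are broken toward the smallest C, then the smallest gamma.
#'
#' @param x subjects x features matrix.
#' @param labels integer vector in {+1, -1}; both classes required.
#' @param cost_grid,gamma_grid candidate values (see [default_svm_grids()]).
#' @param k CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return a [kernel_params()] with attributes `accuracy` (the winning mean
#'   CV accuracy) and `table` (the full grid with accuracies).
#' @export
svm_grid_search <- function(x, labels, cost_grid = default_svm_grids()$cost,
                            gamma_grid = default_svm_grids()$gamma,
                            k = 5L, seed = 1L) {
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (!length(cost_grid) || !length(gamma_grid)) stop("empty parameter grid")
  x <- as.matrix(x)
  set.seed(seed)
  folds <- make_folds(labels, k)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- kernel_params(grid$cost[g], grid$gamma[g])
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- fit_rbf_svm(x[tr, , drop = FALSE], labels[tr], p)
      correct <- correct +
        sum(svm_predict_labels(model, x[!tr, , drop = FALSE]) == labels[!tr])
    }
    acc[g] <- correct / length(labels)
  }
  best <- order(-acc, grid$cost, grid$gamma)[1L]
  out <- kernel_params(grid$cost[best], grid$gamma[best])
  attr(out, "accuracy") <- acc[best]
  attr(out, "table") <- cbind(grid, accuracy = acc)
  out
}
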