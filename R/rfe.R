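#' Kernel-space elimination criterion
#'
#' For a trained RBF-kernel SVM, the contribution of feature f to the margin
#' objective is measured by the change in the quadratic form
#' J = 1/2 sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j) when the kernel is
#' recomputed with feature f removed, the dual coefficients held fixed:
#' dJ(f) = 1/2 a' H a - 1/2 a' H_(-f) a. Features with the smallest dJ
#' contribute least to the margin and are eliminated first. For the RBF
#' kernel, removing feature f multiplies K elementwise by
#' exp(gamma * (x_if - x_jf)^2), so all dJ values are computed from one
#' support-vector kernel matrix.
#'
#' @param model a fitted `e1071::svm` RBF model trained with `scale = FALSE`.
#' @param gamma the kernel gamma the model was trained with.
#' @return numeric vector of dJ values, one per feature column.
#' @export
rfe_delta_j <- function(model, gamma) {
  SV <- as.matrix(model$SV)
  a <- as.numeric(model$coefs) # alpha_i * y_i
  K <- exp(-gamma * as.matrix(stats::dist(SV))^2)
  A <- (a %o% a) * K
  J <- sum(A)
  vapply(seq_len(ncol(SV)), function(f) {
    Df <- outer(SV[, f], SV[, f], `-`)^2
    0.5 * (J - sum(A * exp(gamma * Df)))
  }, numeric(1))
}

#' Nonlinear SVM recursive feature elimination
#'
#' Iteratively trains the RBF-kernel SVM on the surviving features, scores
#' each by [rfe_delta_j()], and eliminates the lowest-scoring ones until all
#' are ranked. A fraction of the survivors is dropped per round while many
#' remain, then one at a time. Ties are broken toward the lower column
#' index (eliminated first, i.e. ranked worse).
#'
#' @param x subjects x features matrix (screened features).
#' @param labels integer vector in {+1, -1}.
#' @param params a [kernel_params()].
#' @param fraction fraction of survivors eliminated per round (default 0.1).
#' @param one_by_one_below switch to single elimination when at most this
#'   many features survive (default 100).
#' @return an `rfe_ranking`: list with `ranking` (best first, original column
#'   indices) and `elimination_order` (worst first).
#' @export
rfe_rank <- function(x, labels, params, fraction = 0.1,
                     one_by_one_below = 100L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("RFE needs at least two features")
  surviving <- seq_len(ncol(x))
  eliminated <- integer(0)
  iter <- 0L
  while (length(surviving) > 1L) {
    iter <- iter + 1L
    model <- tryCatch(
      fit_rbf_svm(x[, surviving, drop = FALSE], labels, params),
      error = function(e) stop(sprintf(
        "SVM training failed at elimination iteration %d: %s",
        iter, conditionMessage(e)), call. = FALSE))
    dj <- rfe_delta_j(model, params$gamma)
    n_drop <- if (length(surviving) > one_by_one_below) {
      max(1L, floor(fraction * length(surviving)))
    } else 1L
    # order() is stable, so equal dJ resolves to the lower column index
    drop_pos <- order(dj)[seq_len(n_drop)]
    eliminated <- c(eliminated, surviving[sort(drop_pos)])
    surviving <- surviving[-drop_pos]
  }
  eliminated <- c(eliminated, surviving)
  structure(list(ranking = rev(eliminated), elimination_order = eliminated),
            class = "rfe_ranking")
}

#' AUC-based optimal subset selection
#'
#' Evaluates the cross-validated AUC of the RBF-kernel classifier on the
#' top-n ranked features for each n up to `n_max` and selects the subset
#' maximizing AUC (ties toward the smallest n — class imbalance makes AUC
#' the selection criterion of choice). Reported per-feature weights are the
#' rank positions of the selected subset rescaled linearly to [1, 0]
#' (best = 1.00, worst = 0.00).
#'
#' @param ranking an `rfe_ranking` (or integer vector, best first).
#' @param x,labels the feature matrix and labels available to selection.
#' @param params a [kernel_params()].
#' @param n_max largest subset size scanned (default `min(200, n ranked)`).
#' @param k inner CV folds for the AUC estimate (default 5).
#' @param seed integer seed for fold assignments.
#' @return an `rfe_result`: list with `ranking`, `auc_curve` (data.frame
#'   n, auc), `optimal_n`, `optimal_columns` (original column indices) and
#'   `weights` (named by column, rescaled rank scores).
#' @export
select_optimal_subset <- function(ranking, x, labels, params,
                                  n_max = NULL, k = 5L, seed = 1L) {
  if (inherits(ranking, "rfe_ranking")) ranking <- ranking$ranking
  x <- as.matrix(x)
  if (is.null(n_max)) n_max <- min(200L, length(ranking))
  n_max <- min(n_max, length(ranking))
  set.seed(seed)
  auc <- numeric(n_max)
  for (n in seq_len(n_max)) {
    cols <- ranking[seq_len(n)]
    cv <- cv_scores(x[, cols, drop = FALSE], labels, params, k = k)
    auc[n] <- roc_auc(cv$scores, labels)$auc
  }
  optimal_n <- which.max(auc) # ties -> smallest n
  cols <- ranking[seq_len(optimal_n)]
  weights <- if (optimal_n == 1L) 1 else seq(1, 0, length.out = optimal_n)
  names(weights) <- cols
  structure(list(ranking = ranking,
                 auc_curve = data.frame(n = seq_len(n_max), auc = auc),
                 optimal_n = optimal_n, optimal_columns = cols,
                 weights = weights),
            class = "rfe_result")
}
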