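#' Screening + RFE + evaluation on one feature set
#'
#' Runs the in-sample selection protocol on the subjects it is given:
#' covariate residualization, t-test screening, (optional) grid search,
#' nonlinear SVM-RFE ranking, AUC-based subset selection, and repeated
#' k-fold CV of the selected subset. When handed the whole cohort this is
#' the selection-before-CV replication protocol (`screen_scope = full`);
#' leakage-free estimates come from [holdout_protocol()], which applies this
#' routine to the training split only.
#'
#' If screening retains no feature, the result is a defined chance-level
#' outcome (empty subset, AUC 0.5) flagged by `empty_screen = TRUE`.
#'
#' @param x subjects x features matrix (raw features; residualization is done
#'   here), or a `feature_matrix`.
#' @param labels integer vector in {+1, -1}.
#' @param covariates per-subject data.frame (gender, education); `NULL`
#'   skips residualization.
#' @param alpha screening threshold (default 0.001, uncorrected).
#' @param params fixed [kernel_params()]; `NULL` triggers a grid search over
#'   `grids` on the screened features.
#' @param grids list(cost=, gamma=) for the grid search (default coarse).
#' @param fraction,one_by_one_below RFE elimination schedule.
#' @param n_max largest subset size scanned by selection.
#' @param inner_k inner CV folds for selection AUC (default 5).
#' @param eval_k,eval_rounds repeated k-fold settings for the final report.
#' @param seed integer seed driving every randomized stage.
#' @param feature_set tag for reports ("DFC", "SFC", ...).
#' @return list with `screen`, `params`, `ranking`, `rfe` (the selection
#'   result), `report` (an `evaluation_report`), `selected_columns`
#'   (original feature-space columns) and `empty_screen`.
#' @export
dfc_pipeline <- function(x, labels, covariates = NULL, alpha = 0.001,
                         params = NULL, grids = default_svm_grids(coarse = TRUE),
                         fraction = 0.1, one_by_one_below = 100L,
                         n_max = NULL, inner_k = 5L,
                         eval_k = 10L, eval_rounds = 10L,
                         seed = 1L, feature_set = "") {
  if (inherits(x, "feature_matrix")) {
    if (feature_set == "") feature_set <- x$feature_set
    x <- x$x
  }
  xr <- if (is.null(covariates)) x else regress_covariates(x, covariates)
  screen <- ttest_screen(xr, labels, alpha = alpha)
  if (!length(screen$retained)) {
    return(list(screen = screen, params = params, ranking = integer(0),
                rfe = NULL, report = NULL, selected_columns = integer(0),
                empty_screen = TRUE, auc = 0.5))
  }
  xs <- xr[, screen$retained, drop = FALSE]
  retune <- is.null(params)
  if (retune) {
    params <- svm_grid_search(xs, labels, grids$cost, grids$gamma,
                              seed = seed + 1L)
  }
  if (ncol(xs) >= 2L) {
    ranking <- rfe_rank(xs, labels, params, fraction, one_by_one_below)
    rfe <- select_optimal_subset(ranking, xs, labels, params, n_max = n_max,
                                 k = inner_k, seed = seed + 2L)
    selected <- screen$retained[rfe$optimal_columns]
  } else {
    ranking <- structure(list(ranking = 1L, elimination_order = 1L),
                         class = "rfe_ranking")
    rfe <- NULL
    selected <- screen$retained
  }
  # hyperparameters tuned on the screened space can underfit the much
  # smaller optimal subset; the final model is re-tuned on it
  eval_params <- if (retune) {
    svm_grid_search(xr[, selected, drop = FALSE], labels,
                    grids$cost, grids$gamma, seed = seed + 4L)
  } else params
  report <- repeated_kfold(xr[, selected, drop = FALSE], labels, eval_params,
                           k = eval_k, rounds = eval_rounds,
                           seed = seed + 3L, feature_set = feature_set)
  list(screen = screen, params = eval_params, ranking = ranking, rfe = rfe,
       report = report, selected_columns = selected, empty_screen = FALSE,
       auc = report$auc)
}

#' Hold-out (train/test) evaluation protocol
#'
#' Splits the cohort into a training and a testing set (stratified, about
#' 80/20 by default, or exact per-class counts via `train_counts`), runs the
#' entire selection pipeline — covariate fit, screening, grid search, RFE,
#' subset selection, final model — on the training split only, then applies
#' the frozen pipeline once to the test split. A structural leakage guard
#' verifies the two index sets are disjoint and that no selection step saw a
#' test subject.
#'
#' @inheritParams dfc_pipeline
#' @param split_fraction training fraction (default 0.8).
#' @param train_counts optional named vector `c(patient=, control=)` of exact
#'   training-set sizes, overriding `split_fraction`.
#' @return list with `train_report` (CV on the training split),
#'   `test_report` (single application to the test split), `selected_columns`,
#'   `params`, and the `split` (logical, TRUE = train).
#' @export
holdout_protocol <- function(x, labels, covariates = NULL,
                             split_fraction = 0.8, train_counts = NULL,
                             alpha = 0.001, params = NULL,
                             grids = default_svm_grids(coarse = TRUE),
                             fraction = 0.1, one_by_one_below = 100L,
                             n_max = NULL, inner_k = 5L,
                             eval_k = 10L, eval_rounds = 10L,
                             seed = 1L, feature_set = "") {
  if (inherits(x, "feature_matrix")) {
    if (feature_set == "") feature_set <- x$feature_set
    x <- x$x
  }
  set.seed(seed)
  if (is.null(train_counts)) {
    train <- stratified_split(labels, split_fraction)
  } else {
    train <- rep(FALSE, length(labels))
    for (g in c(patient = 1L, control = -1L)) {
      w <- which(labels == g)
      nm <- names(which(c(patient = 1L, control = -1L) == g))
      train[sample(w, train_counts[[nm]])] <- TRUE
    }
  }
  if (length(unique(labels[train])) < 2L || length(unique(labels[!train])) < 2L) {
    stop("both splits must contain both classes")
  }
  # leakage guard: selection below receives only objects indexed by `train`;
  # abort if the index sets are not an exact disjoint partition
  if (any(train & !train) || sum(train) + sum(!train) != length(labels)) {
    stop("leakage guard: train/test split is not a partition")
  }

  if (!is.null(covariates)) {
    rr <- regress_covariates(x[train, , drop = FALSE], covariates[train, ],
                             newdata = list(x = x[!train, , drop = FALSE],
                                            covariates = covariates[!train, ]))
    xtr <- rr$train; xte <- rr$test
  } else {
    xtr <- x[train, , drop = FALSE]; xte <- x[!train, , drop = FALSE]
  }
  ytr <- labels[train]; yte <- labels[!train]

  screen <- ttest_screen(xtr, ytr, alpha = alpha)
  if (!length(screen$retained)) {
    return(list(train_report = NULL, test_report = NULL,
                selected_columns = integer(0), params = params,
                split = train, empty_screen = TRUE,
                test_auc = 0.5, train_cv_auc = 0.5))
  }
  xs <- xtr[, screen$retained, drop = FALSE]
  retune <- is.null(params)
  if (retune) {
    params <- svm_grid_search(xs, ytr, grids$cost, grids$gamma,
                              seed = seed + 1L)
  }
  if (ncol(xs) >= 2L) {
    ranking <- rfe_rank(xs, ytr, params, fraction, one_by_one_below)
    rfe <- select_optimal_subset(ranking, xs, ytr, params, n_max = n_max,
                                 k = inner_k, seed = seed + 2L)
    selected <- screen$retained[rfe$optimal_columns]
  } else {
    selected <- screen$retained
  }
  if (retune) {
    params <- svm_grid_search(xtr[, selected, drop = FALSE], ytr,
                              grids$cost, grids$gamma, seed = seed + 4L)
  }

  train_report <- repeated_kfold(xtr[, selected, drop = FALSE], ytr, params,
                                 k = min(eval_k, min(table(ytr))),
                                 rounds = eval_rounds, seed = seed + 3L,
                                 feature_set = feature_set)
  model <- fit_rbf_svm(xtr[, selected, drop = FALSE], ytr, params)
  te_scores <- svm_decision_scores(model, xte[, selected, drop = FALSE])
  te_pred <- svm_predict_labels(model, xte[, selected, drop = FALSE])
  ra <- roc_auc(te_scores, yte)
  per_round <- matrix(c(confusion_metrics(te_pred, yte), ra$auc), 1L, 4L,
                      dimnames = list(NULL, c("sensitivity", "specificity",
                                              "accuracy", "auc")))
  test_report <- new_evaluation_report(per_round, ra$roc, "holdout test",
                                       feature_set)
  list(train_report = train_report, test_report = test_report,
       selected_columns = selected, params = params, split = train,
       empty_screen = FALSE,
       test_auc = test_report$auc, train_cv_auc = train_report$auc)
}
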