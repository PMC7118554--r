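#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney probability that a randomly chosen
#' patient (+1) scores above a randomly chosen control (-1), ties counted
#' one half — identical to the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric decision scores, larger favouring the patient class.
#' @param labels integer vector in {+1, -1}; both classes required.
#' @return list with `auc` and `roc` (data.frame `threshold`, `fpr`, `tpr`,
#'   stepping through the distinct score thresholds from +Inf down).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1L; neg <- labels == -1L
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores) # midranks: ties count one half
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[neg] >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))))
  list(auc = auc, roc = roc)
}

confusion_metrics <- function(predicted, labels) {
  pos <- labels == 1L; neg <- labels == -1L
  sens <- mean(predicted[pos] == 1L)
  spec <- mean(predicted[neg] == -1L)
  acc <- mean(predicted == labels)
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

new_evaluation_report <- function(per_round, roc, protocol, feature_set) {
  means <- colMeans(per_round)
  sds <- apply(per_round, 2L, stats::sd)
  structure(list(
    sensitivity = means[["sensitivity"]], specificity = means[["specificity"]],
    accuracy = means[["accuracy"]], auc = means[["auc"]],
    per_round = per_round, sd = sds, roc = roc,
    protocol = protocol, feature_set = feature_set),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s%s]\n", x$protocol,
              if (nzchar(x$feature_set)) paste0(", ", x$feature_set) else ""))
  cat(sprintf("  sensitivity %5.2f%%  specificity %5.2f%%  accuracy %5.2f%%  AUC %.4f\n",
              100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy, x$auc))
  if (nrow(x$per_round) > 1L) {
    cat(sprintf("  across %d rounds: AUC sd %.4f, accuracy sd %.4f\n",
                nrow(x$per_round), x$sd[["auc"]], x$sd[["accuracy"]]))
  }
  invisible(x)
}

#' Repeated stratified k-fold cross-validation
#'
#' Each round independently shuffles the subjects into k near-equal
#' (stratified by default) folds, trains on k-1 folds and tests on the held
#' one, cycling through all folds; within a round the held-out predictions
#' are pooled into one set of metrics, and the report averages across rounds.
#'
#' @param x subjects x features matrix.
#' @param labels integer vector in {+1, -1}.
#' @param params a [kernel_params()].
#' @param k folds (default 10); must not exceed the smaller group size when
#'   stratified.
#' @param rounds number of independent repetitions (default 100).
#' @param stratified keep the class ratio within folds (default TRUE). Under
#'   non-stratified folding a fold may miss a class; its cells are skipped
#'   with a warning and metrics come from the defined cells only.
#' @param seed integer seed; the fold shuffles are reproducible.
#' @param feature_set tag carried into the report (e.g. "DFC").
#' @return an `evaluation_report` (metrics as fractions; print renders %).
#' @export
repeated_kfold <- function(x, labels, params, k = 10L, rounds = 100L,
                           stratified = TRUE, seed = 1L, feature_set = "") {
  x <- as.matrix(x)
  set.seed(seed)
  per_round <- matrix(NA_real_, rounds, 4L,
                      dimnames = list(NULL, c("sensitivity", "specificity",
                                              "accuracy", "auc")))
  roc <- NULL
  for (r in seq_len(rounds)) {
    folds <- make_folds(labels, k, stratified)
    scores <- numeric(length(labels)); pred <- integer(length(labels))
    tested <- rep(FALSE, length(labels))
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(labels[tr])) < 2L) {
        warning(sprintf("round %d fold %d: training data single-class; fold skipped",
                        r, f))
        next
      }
      model <- fit_rbf_svm(x[tr, , drop = FALSE], labels[tr], params)
      scores[!tr] <- svm_decision_scores(model, x[!tr, , drop = FALSE])
      pred[!tr] <- svm_predict_labels(model, x[!tr, , drop = FALSE])
      tested[!tr] <- TRUE
    }
    ra <- roc_auc(scores[tested], labels[tested])
    per_round[r, ] <- c(confusion_metrics(pred[tested], labels[tested]),
                        auc = ra$auc)
    if (r == 1L) roc <- ra$roc
  }
  new_evaluation_report(per_round, roc,
                        sprintf("%d-fold x %d rounds", k, rounds), feature_set)
}

#' Leave-one-out cross-validation
#'
#' Each subject is held out in turn; deterministic given the data. With a
#' single-class training remainder (only possible at degenerate n) the model
#' predicts the one remaining class; this is the documented behaviour.
#'
#' @inheritParams repeated_kfold
#' @return an `evaluation_report` (one "round" pooling all subjects).
#' @export
loocv <- function(x, labels, params, feature_set = "") {
  x <- as.matrix(x)
  n <- length(labels)
  scores <- numeric(n); pred <- integer(n)
  for (s in seq_len(n)) {
    tr <- seq_len(n) != s
    ytr <- labels[tr]
    if (length(unique(ytr)) < 2L) {
      pred[s] <- unique(ytr)
      scores[s] <- unique(ytr) * Inf
      next
    }
    model <- fit_rbf_svm(x[tr, , drop = FALSE], ytr, params)
    scores[s] <- svm_decision_scores(model, x[s, , drop = FALSE])
    pred[s] <- svm_predict_labels(model, x[s, , drop = FALSE])
  }
  ra <- roc_auc(scores, labels)
  per_round <- matrix(c(confusion_metrics(pred, labels), ra$auc), 1L, 4L,
                      dimnames = list(NULL, c("sensitivity", "specificity",
                                              "accuracy", "auc")))
  new_evaluation_report(per_round, ra$roc, "loocv", feature_set)
}

#' Stratified train/test split
#'
#' @param labels integer vector in {+1, -1}.
#' @param split_fraction training fraction (default 0.8).
#' @return logical vector, TRUE = training subject. Uses the current RNG.
#' @export
stratified_split <- function(labels, split_fraction = 0.8) {
  train <- rep(FALSE, length(labels))
  for (g in unique(labels)) {
    w <- which(labels == g)
    n_tr <- round(split_fraction * length(w))
    if (n_tr < 1L || n_tr >= length(w)) {
      stop("split leaves a class empty on one side")
    }
    train[sample(w, n_tr)] <- TRUE
  }
  train
}
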