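#!/usr/bin/env Rscript
# Performance estimation: the DFC and SFC pipelines under repeated
# stratified 10-fold CV, LOOCV on the selected DFC subset, and the
# leakage-free 80/20 hold-out protocol (33+40 train / 10+16 test).

library(dfcmdd)

seed <- 1L
cohort <- generate_cohort(demo_cohort_spec(n_patients = 43L,
                                           n_controls = 56L, seed = seed))
y <- cohort_labels(cohort)
cov <- cohort_covariates(cohort)

rows <- list()
for (mode in c("dfc", "sfc")) {
  fm <- build_features(cohort, mode)
  fit <- dfc_pipeline(fm, y, cov, grids = study_grids(), n_max = 40L,
                      eval_k = 10L, eval_rounds = 10L, seed = seed)
  r <- fit$report
  rows[[mode]] <- data.frame(
    protocol = r$protocol, feature_set = toupper(mode),
    n_features = length(fit$selected_columns),
    sensitivity_pct = 100 * r$sensitivity,
    specificity_pct = 100 * r$specificity,
    accuracy_pct = 100 * r$accuracy, auc = r$auc)
  if (mode == "dfc") {
    xr <- regress_covariates(fm$x, cov)
    lo <- loocv(xr[, fit$selected_columns, drop = FALSE], y, fit$params,
                feature_set = "DFC")
    rows$loocv <- data.frame(
      protocol = "loocv", feature_set = "DFC",
      n_features = length(fit$selected_columns),
      sensitivity_pct = 100 * lo$sensitivity,
      specificity_pct = 100 * lo$specificity,
      accuracy_pct = 100 * lo$accuracy, auc = lo$auc)
    ho <- holdout_protocol(fm$x, y, cov,
                           train_counts = c(patient = 33, control = 40),
                           grids = study_grids(), n_max = 40L,
                           eval_rounds = 5L, seed = seed)
    rows$holdout <- data.frame(
      protocol = c("holdout train CV", "holdout test"), feature_set = "DFC",
      n_features = length(ho$selected_columns),
      sensitivity_pct = 100 * c(ho$train_report$sensitivity,
                                ho$test_report$sensitivity),
      specificity_pct = 100 * c(ho$train_report$specificity,
                                ho$test_report$specificity),
      accuracy_pct = 100 * c(ho$train_report$accuracy,
                             ho$test_report$accuracy),
      auc = c(ho$train_report$auc, ho$test_report$auc))
  }
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/performance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Performance on the demonstration cohort (transient planted effects):\n\n")
print(tab, digits = 4, row.names = FALSE)
cat("\nThe DFC pipeline dominates SFC because the planted group differences",
    "\nare confined to epochs and dilute over the whole series.\n")
cat("Table in results/performance.tsv\n")
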