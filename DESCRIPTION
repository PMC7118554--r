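Package: dfcmdd
Title: Dynamic Functional Connectivity Classification of Major Depressive Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sliding-window dynamic functional connectivity (DFC) analysis and
    classification of major depressive disorder from region-of-interest fMRI
    time series. Provides a synthetic-cohort generator with planted,
    window-localized connectivity effects and clinical-score couplings;
    sliding-window and static Pearson connectivity tensors with indexed
    vectorization; covariate residualization and two-sample t-test screening;
    nonlinear (RBF-kernel) SVM recursive feature elimination with AUC-based
    optimal subset selection; repeated stratified k-fold, leave-one-out and
    hold-out evaluation protocols with ROC/AUC; and spatiotemporal mapping of
    selected connections onto an atlas with clinical correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
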