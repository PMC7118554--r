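# dfcmdd

Sliding-window **dynamic functional connectivity (DFC)** analysis and
SVM-based classification of major depressive disorder (MDD) from
region-of-interest (ROI) fMRI time series — with a synthetic-cohort
generator that plants *known*, window-localized connectivity effects so
that every stage of the pipeline can be validated against ground truth.

## The problem

Resting-state functional connectivity between brain regions is usually
summarized by one Pearson correlation per region pair over the whole scan
(static functional connectivity, SFC). But group differences that are
confined to transient epochs of the scan — present for a minute, absent
otherwise — are diluted in the whole-series correlation and can be
invisible to SFC. Sliding-window DFC resolves them: for a series of
*T* timepoints, windows of width *w* advanced by step *s* yield
*W* = ⌊(*T* − *w*)/*s*⌋ + 1 correlation matrices per subject. At the
scale this package emulates (*T* = 200 at TR = 2 s, *w* = 50, *s* = 2,
273 regions) that is 76 windows × 37,128 region pairs = 2,821,728
candidate features per subject, from which a classifier must find the few
connections that discriminate patients from controls.

## The pipeline

1. **Simulation** (`generate_cohort`): piecewise-stationary Gaussian ROI
   series with epochwise target correlations (baseline for controls,
   baseline + δ on planted edges for patients during their epochs),
   band-limited to 0.01–0.1 Hz by an exact Fourier mask; confounded
   gender/education covariates; HAMD/HAMA scores linearly coupled to
   designated edge correlations. Ground truth is returned alongside.
2. **Feature extraction** (`build_features`): windowed or whole-series
   Pearson tensors, vectorized window-major over the row-major upper
   triangle, with an invertible column ↔ (window, *i*, *j*) index.
3. **Screening** (`regress_covariates`, `ttest_screen`): least-squares
   residualization on gender and education, then a pooled-variance
   two-sample *t*-test keeping columns with *p* < 0.001 (uncorrected).
4. **Nonlinear SVM-RFE** (`rfe_rank`, `select_optimal_subset`): RBF-kernel
   SVM with grid-searched (C, γ); each surviving feature *f* scored by the
   kernel-space margin criterion ΔJ(*f*) = ½ αᵀHα − ½ αᵀH₍₋f₎α (dual
   coefficients held fixed, kernel recomputed without *f*); lowest-ΔJ
   features eliminated iteratively; the optimal subset is the top-*n*
   prefix maximizing cross-validated AUC.
5. **Evaluation** (`repeated_kfold`, `loocv`, `holdout_protocol`,
   `roc_auc`): repeated stratified 10-fold CV, LOOCV, and a leakage-free
   80/20 hold-out in which *all* selection runs on the training split
   only. AUC is the Mann–Whitney probability of correct ordering (ties ½).
6. **Characterization** (`map_connections`, `node_degrees`,
   `clinical_correlation`): selected columns decoded to windows (in scan
   seconds), region pairs and networks via an atlas table; node degrees;
   covariate-adjusted Pearson correlations with HAMD/HAMA in patients.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
demonstration cohort (43 patients / 56 controls, 30 regions, three planted
transient edges with |δ| = 0.5). `Rscript analysis/05_evaluate.R` prints:

```
 protocol            feature_set n_features sensitivity_pct specificity_pct accuracy_pct    auc
 10-fold x 10 rounds         DFC         39           84.65           90.71        88.08 0.9447
 loocv                       DFC         39           86.05           91.07        88.89 0.9468
 holdout train CV            DFC         36           87.88           90.00        89.04 0.9518
 holdout test                DFC         36           90.00           87.50        88.46 0.9688
 10-fold x 10 rounds         SFC          3           71.86           85.89        79.80 0.8773
```

The DFC pipeline beats the SFC pipeline by ~0.07 AUC here because the
planted group differences occupy only ~35% of the scan: windowed
correlations see them at full strength, the whole-series correlation at a
third. `analysis/04_select_features.R` reports that the AUC curve over
top-*n* subsets peaks at 39 features covering exactly the three planted
edges, and `analysis/06_characterize.R` maps them to windows/networks and
recovers the planted HAMD/HAMA couplings (strongest adjusted correlation
r = −0.61 with HAMA).

A minimal programmatic session:

```r
library(dfcmdd)
cohort <- generate_cohort(demo_cohort_spec(seed = 3))
fm  <- build_features(cohort, "dfc")
fit <- dfc_pipeline(fm, cohort_labels(cohort), cohort_covariates(cohort),
                    grids = study_grids(), n_max = 60, seed = 3)
fit$report
#> evaluation_report [10-fold x 10 rounds, DFC]
#>   sensitivity 93.25%  specificity 87.00%  accuracy 90.12%  AUC 0.9764
#>   across 10 rounds: AUC sd 0.0019, accuracy sd 0.0138
decode_features(fm$index, fit$selected_columns)  # (window, i, j) triples
```

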