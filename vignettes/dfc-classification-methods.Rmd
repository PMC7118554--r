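---
title: "Dynamic functional connectivity classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dfcmdd)
```

This vignette is the package's own account of its methods: the generative
model behind the synthetic cohorts, the statistics of each pipeline stage,
the tunable parameters with their defaults and rationale, the numerical
conventions, and the design decisions that were genuinely open. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Why dynamic connectivity

A group difference in the coupling of two brain regions that is present
only during part of a resting-state scan — a *transient* or
*window-localized* effect — appears in the whole-series Pearson
correlation (static functional connectivity, SFC) only in diluted form:
if the effect of size $\delta$ occupies a fraction $\phi$ of the scan, the
static correlation shifts by roughly $\phi\delta$. Sliding-window dynamic
functional connectivity (DFC) computes the correlation inside windows of
width $w$ advanced by step $s$, so windows inside the epoch see the full
$\delta$. The package's central, testable claim is therefore comparative:
on cohorts whose group differences are confined to epochs, a classifier
built on DFC features outperforms the same classifier built on SFC
features.

## The synthetic cohort model

`generate_cohort()` draws each subject's $T \times N$ ROI series from a
piecewise-stationary Gaussian model:

1. the scan is segmented at the planted epoch boundaries; each segment has
   a target correlation matrix $R$ — the identity plus the configured
   baseline on planted edges for controls, plus $\delta$ on each planted
   edge during its epoch for patients;
2. i.i.d. standard-normal innovations are transformed by the Cholesky
   factor of the segment's $R$ (a jointly infeasible $R$ — not positive
   definite — is rejected with the offending edge set named);
3. the whole series is band-limited to the configured band (default
   0.01–0.1 Hz at TR = 2 s) by an exact Fourier mask that zeroes every
   out-of-band coefficient, DC included.

The Fourier mask was chosen over an IIR filter because it is linear,
exactly band-confining (the spectral-mass invariant — over 90% of variance
in band — holds by construction and is still tested), and free of edge
transients and stability concerns. Because the same linear filter is
applied to every channel, in-band cross-correlations are preserved in
expectation; the cost is some temporal smearing of epoch boundaries by the
mask's impulse response, so the measured within-epoch correlation
difference between groups is mildly attenuated (the Monte-Carlo test
recovers a planted $\delta = 0.5$ to within $\pm 0.1$). Correlating before
filtering keeps the epoch targets exact in the unfiltered model; a
`band = NULL` switch disables filtering for exact-correlation unit tests.

Band-limiting also sets the window width: the conventional lower bound is
the period of the slowest retained frequency, $1/f_{\min} = 100$ s, i.e.
50 timepoints at TR = 2 s (`min_window_width(0.01, 2)`), which is the
default `window_width`. The default step is 2 timepoints, giving
$W = \lfloor (200-50)/2 \rfloor + 1 = 76$ windows.

**Default study conditions.** The demonstration spec
(`demo_cohort_spec()`) uses 30 regions, 200 timepoints, and three planted
edges of $|\delta| = 0.5$ over 70-timepoint epochs — (1,2) on $[40,110)$,
(3,4) with negative sign on $[90,160)$, (5,6) on $[20,90)$. Each epoch
fully contains 11 sliding windows; $\phi = 0.35$, so SFC sees shifts of
about $0.17$. Group sizes default to 40/40 for recovery studies and 43/56
for cohort-shaped analyses. Effect size 0.5 is a large but realistic
connectivity difference; 30 regions keep the full DFC feature space
(33,060 columns) tractable on a desk while preserving the
needle-in-a-haystack character of the problem. The 273-region default of
`cohort_spec()` reproduces the full-scale dimensional arithmetic
(76 × 37,128 = 2,821,728 features) and is exercised for its arithmetic,
not simulated in the tests.

**Covariates and clinical scores.** Gender and education are drawn from
group-specific models matching the emulated cohort's demographics (male
rate 13/43 vs 30/56; education 11.44 ± 3.33 vs 15.78 ± 4.33 years), so
education is *confounded* with group (r ≈ 0.5) exactly as in the data the
pipeline replicates. The generator does not model a direct covariate
effect on the signal: the confound acts through the label, which is what
makes residualization consequential (below). Clinical scores exist for
patients only and are linear in the subject's mean windowed correlation of
a designated edge over a designated window range, plus Gaussian noise,
rounded to integers (rating scales are integer sums of items). The
defaults couple HAMD to edge (1,2) over windows 21–31 and HAMA
(negatively) to edge (3,4) over windows 46–56, with coefficients and noise
calibrated so the population feature–score correlation is about 0.6 in
magnitude and the score moments sit near 23.4/18.0 (means) and 2.7–2.9
(sd). The across-subject sd of the coupled feature is itself a derived
quantity (~0.17), dominated by the low effective degrees of freedom of
band-limited 50-point windows; the calibration was done against that
measured value at large n.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamics and spatial structure (no
volumetric data, no point-spread), head motion and physiological
nuisance, heavy-tailed and nonstationary noise, autocorrelated scanner
drifts, network-structured baseline connectivity (the baseline is
diagonal), and direct covariate effects on the signal. The pipeline's
statistical machinery is validated here; its clinical performance on real
fMRI is not a claim this package can make.

## Screening

Each feature column is replaced by the residuals of a least-squares fit
on an intercept, gender and education (`regress_covariates`; QR-based,
matching the normal equations to 1e-10 in the oracle tests; constant
covariates are dropped, collinear designs are an error). For hold-out
evaluation the fit estimated on the training split is applied to the test
split — residualizing the pooled data would leak test information.

Screening then keeps columns whose pooled-variance two-sample $t$-test
(Student; Welch by flag — pooled is the convention of the classical
statistics packages this protocol mirrors) gives $p < \alpha$, default
$\alpha = 0.001$ uncorrected, the screening convention of the replicated
protocol. Degenerate zero-variance columns get $p = 1$.

A consequence worth stating: on effect-free data the *operation* is
exactly calibrated (retained fraction ≈ α, verified binomially on $10^5$
i.i.d. features), but the *protocol* — residualize on a group-correlated
covariate, then t-test — is conservative in the far tail, because the
covariate absorbs part of any chance group difference while the residual
degrees of freedom are not adjusted. The acceptance checks therefore
require the protocol's null retained fraction to be at most ≈ α (no
inflation) rather than equal to it, and verify exact calibration under
label permutation, where the confound is broken. Windowed-correlation
features are also platykurtic and strongly dependent across overlapping
windows, so cohort-level retained fractions get a dependence-widened
tolerance rather than a binomial one.

## Nonlinear SVM-RFE

The classifier is the RBF-kernel soft-margin SVM (via `e1071`/libsvm,
`scale = FALSE`; labels +1 patient, −1 control; decision scores oriented
so larger favours patients). Hyperparameters come from a grid search
maximizing mean CV accuracy over power-of-two grids (full grids
$C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$; the desk-scale studies use
the thinned `study_grids()`), ties broken toward the smallest $C$ then
$\gamma$ for reproducibility.

Feature elimination uses the kernel-space margin criterion: with dual
coefficients $\alpha$ and label-weighted kernel $H$ on the support
vectors, feature $f$'s contribution is
$\Delta J(f) = \tfrac12 \alpha^\top H \alpha - \tfrac12 \alpha^\top
H_{(-f)} \alpha$, where $H_{(-f)}$ recomputes the kernel with $f$ removed
and $\alpha$ held fixed. For the RBF kernel the removal is a cheap
elementwise update, $K_{(-f)} = K \odot \exp(\gamma\, d_f)$ with $d_f$ the
pairwise squared differences on $f$. Features with the smallest
$\Delta J$ are eliminated — 10% of survivors per round while more than 100
remain, then one at a time (a schedule balancing fidelity of the ranking
against runtime); ties fall to the lower column index. The criterion is
verified against brute-force kernel sums to 1e-10.

The optimal subset is chosen by scanning the top-$n$ prefixes of the
ranking ($n \le$ `n_max`, default 200) and maximizing cross-validated AUC
(5-fold by default; AUC rather than accuracy because the cohorts are
class-imbalanced), ties to the smallest $n$. Because the ranking is fitted
on the same data, this curve carries selection optimism even on noise —
the calibration test therefore evaluates the curve under a
data-independent ranking, and the optimism itself is quantified separately
(below). Reported per-feature weights are the rank positions of the
selected subset rescaled linearly onto $[1, 0]$ (best = 1.00, worst =
0.00, equal spacing); a margin-based magnitude would also be defensible,
but the rescaled rank reproduces the conventional reporting pattern and is
monotone with the ranking by construction.

After subset selection, $(C, \gamma)$ are re-searched on the selected
columns: parameters tuned on the few-hundred-column screened space can
underfit the order-of-magnitude smaller optimal subset badly enough to
collapse the classifier onto the majority class (observed as high-AUC,
low-sensitivity reports before the re-tune was added).

## Evaluation protocols

* `repeated_kfold`: each round independently shuffles subjects into $k$
  near-equal folds — stratified by default, since the emulated cohort is
  imbalanced — trains on $k-1$ and tests on the held fold, cycling all
  folds; within a round held-out predictions are pooled into one
  sensitivity/specificity/accuracy/AUC set, and the report averages across
  rounds (defaults $k = 10$, 100 rounds; the desk-scale studies use 2–10
  rounds, which the round-to-round sds — about 0.002 on AUC — justify).
* `loocv`: deterministic leave-one-subject-out; at the degenerate $n = 2$
  the single-class remainder model predicts the one remaining class, a
  documented contract rather than an error.
* `holdout_protocol`: stratified ≈ 80/20 split (or exact per-class counts,
  e.g. 33+40 / 10+16), with residualization, screening, grid search, RFE
  and subset selection all fitted on the training split and applied frozen
  to the test split once; a structural guard verifies the split is a
  disjoint partition and no selection step receives test rows.

AUC is computed as the Mann–Whitney probability of correct ordering with
ties counted one half, on decision-function values (not Platt
probabilities — no extra fitted layer); it equals the trapezoidal area
under the empirical ROC to 1e-12 in the property tests.

**Selection-before-CV optimism.** Screening on the whole cohort before CV
— the replication mode of the protocol — leaks test-fold information into
feature selection. The null-calibration study quantifies it: on effect-free
cohorts, whole-cohort screening followed by repeated CV reports AUCs far
above chance, while the leakage-free hold-out test AUC on the same cohorts
stays near 0.5. Both numbers are recomputed by the acceptance script.

## Recovery metrics

Planted-effect recovery (the `study_recovery` driver) scores the selected
subset against ground truth at the *region-pair* level: the Jaccard
overlap between the distinct edges of the AUC-optimal subset and the
planted edges. Window-exact matching is deliberately not the criterion —
at width 50 / step 2, adjacent windows share 96% of their samples, and
whether the pipeline picks the window starting at timepoint 40 or 42 of
the same epoch is not an identifiable distinction. Window localization is
scored separately as the fraction of selected true-edge features whose
window overlaps the planted epoch (windows partially overlapping an epoch
carry most of the effect and are legitimate selections, so overlap — not
containment — is the supported claim).

Clinical-coupling recovery correlates the coupled feature with the score
across the 43 patients after covariate adjustment and checks the
95% Fisher interval against the large-sample coupling measured on a
600-patient reference cohort.

## Numerical conventions and degenerate inputs

* Window intervals are half-open and 0-based internally; reports use
  1-based window indices, and window $w$ spans
  $[(w-1)\,s\,\mathrm{TR},\ ((w-1)\,s + w_\mathrm{len})\,\mathrm{TR})$
  seconds.
* Vectorization is window-major, row-major over the upper triangle
  ($i < j$); the column ↔ triple maps are exact inverses and are
  property-tested over the whole space.
* Rectangular (boxcar) windows; no taper, no within-window detrending
  beyond what Pearson implies (trends are removed upstream in the
  emulated preprocessing). Raw Pearson $r$ is the feature value; no
  Fisher $z$ (the replicated protocol uses raw $r$; $z$ would be a
  monotone per-feature transform and screening/ranking are not invariant
  to it only through variance pooling).
* A zero-variance region inside a window is an error naming the (window,
  region) coordinates; screening of a zero-variance column yields
  $p = 1$; screening that retains nothing produces a defined
  chance-level pipeline result (AUC 0.5, empty subset, flagged) — the
  honest outcome for SFC on strongly transient cohorts — rather than an
  error.
* All stochastic stages (cohort draws, fold shuffles, permutations,
  splits) are seeded; identical configs and seeds reproduce cohorts and
  study artifacts bit-identically (manifest hashes are compared in the
  tests).
* Atlas handling is fully table-driven: regions and their network labels
  (the seven canonical resting-state networks in the synthetic atlas)
  come from a region table, and excluded parcels are simply absent rows —
  no atlas is hard-coded.

## Known limitations

The Gaussian piecewise-stationary model understates the temporal
complexity of real resting-state fluctuations; boxcar windowing is known
to suppress rapidly changing correlations; the elimination schedule and
inner-CV fold count trade ranking fidelity for runtime and are exposed as
parameters; clinical correlations are reported uncorrected (flagged in
the output metadata) to mirror the replicated protocol; and the
feature-level screening threshold is a fixed uncorrected $p$, so the
screened set size scales with the feature space. None of the desk-scale
defaults (30 regions, tens of subjects) should be read as statements
about full-scale performance.
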