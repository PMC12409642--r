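---
title: "Gender-stratified radiomic modelling of disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gender-stratified radiomic modelling of disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gendrad)
```

## The problem

Resectable colorectal liver metastases (CRLM) show highly variable
post-surgical courses: some patients remain disease-free for years, others
progress within months. Radiomics — the extraction of quantitative
intensity, shape and texture features from routine CT — offers a
non-invasive window on that heterogeneity. gendrad implements a
gender-stratified analysis framework for such feature tables: the same
pipeline is run on all patients, on men only and on women only, and the
resulting models are compared. The outcome is binary: progression within
three years, defined as disease-free survival (DFS) of at most 36 months
(a DFS of exactly 36.0 months counts as progression).

The pipeline has three stages, applied per stratum in fixed order:

1. **Stability feature selection** — features significant in a rank-sum
   test across many random subsamples are retained;
2. **Confounder screening** — patients persistently misclassified by a
   five-classifier panel are removed;
3. **Ensemble evaluation** — an AUC-weighted soft-voting ensemble is
   scored by repeated stratified 10-fold cross-validation.

Patient and feature counts are logged after every stage and can only
shrink. The "all" stratum runs its own independent selection and
screening; it is not a union of the gender-specific results.

## The feature space

CT radiomic extraction with standard settings yields 1316 features per
patient: 93 intensity/texture features (18 first-order, 24 GLCM, 16 GLRLM,
16 GLSZM, 5 NGTDM, 14 GLDM) on the original image and on 13 derived images
(8 wavelet decompositions, Laplacian-of-Gaussian at sigma 1 mm, square,
square root, exponential, logarithm), plus 14 shape features on the
original image only. `generate_feature_names()` reproduces this taxonomy
with PyRadiomics naming (`wavelet-LHL_glcm_Contrast`, ...), so synthetic
tables are column-compatible with real extractions.

## Stability selection

`select_features()` draws `n_rounds` (default 500) class-stratified
subsamples of `subsample_frac` (default 80%) of the patients without
replacement, tests every feature between outcome groups with a two-sided
rank-sum test, and retains features significant (p < `alpha`, default
0.05, strict) in at least `freq_threshold` (default 40%, inclusive) of
rounds. Stratification keeps the ~60/40 prevalence in every round and
makes empty-class rounds impossible at realistic sizes; subsample sizes
round up, with largest-remainder apportionment across the two classes.
The same subsample is used for all features within a round.

The rank-sum p-value uses the exact null distribution when both groups
have at most 12 observations and no ties, and a tie-corrected,
continuity-corrected normal approximation otherwise; features enter the
test untransformed since rank tests are invariant to monotone
transformations.

One behaviour of this procedure deserves emphasis, because it is easy to
misread: the selection frequency of a feature does **not** concentrate
near `alpha` under the null. Because every round draws 80% of the same
cohort, round-level p-values are strongly correlated with the full-sample
p-value, and any feature whose full-sample p happens to fall below about
0.04 will be significant in 40% or more of rounds. The procedure therefore
selects roughly 4–5% of pure-noise features (the package's test suite
measures this directly). Consequently two disjoint strata will typically
share a handful of spuriously selected features even when their true
signal sets are disjoint. Raising the frequency threshold or lowering
alpha would reduce this rate; the defaults deliberately mirror the
established procedure instead.

## Confounder screening

`run_confounder_screen()` trains the five-classifier panel — random
forest, RBF-kernel SVM, single-hidden-layer MLP, logistic regression and
Gaussian naive Bayes — on `n_rounds` (default 500) stratified 80%
subsamples and scores the held-out 20% **out-of-sample** (in-sample
scoring would be degenerate: a random forest reproduces its training
labels almost perfectly, which would make per-patient rates
uninformative). Each patient's correct-classification rate is averaged
over all (round, learner) evaluations in which they were held out;
patients strictly below the first quartile (linear-interpolation quantile)
of that distribution are flagged and removed.

Two properties follow from the rule, not from the data: the screen always
removes roughly a quarter of the cohort, even on noiseless data (up to the
discreteness of one patient at cohort sizes not divisible by four), and
retained patients are by construction those the panel can classify. The
second point matters when interpreting downstream performance (see
*Limitations*).

Features are standardised by training-subsample mean/SD in every round;
learner hyperparameters are ecosystem defaults except for a fixed modest
MLP architecture (5 hidden units, weight decay 0.1); all random
initialisations draw from the R stream, so the screen is reproducible
bit-for-bit under its seed. SVM class probabilities come from Platt
scaling of the decision values, fitted on the training data, which keeps
the fit deterministic.

## Ensemble and thresholding

`fit_ensemble()` estimates each learner's AUC by inner stratified 5-fold
cross-validation on the training data (out-of-fold scores pooled, one AUC
per learner), normalises the raw AUCs to sum to one, and refits the
learners on the full training set. Inner-CV AUC is used rather than
resubstitution AUC (which would overweight overfitters) or test-set AUC
(which would leak). AUCs below 0.5 are kept as raw weights with a warning
rather than floored — the weighting rule uses the AUC values as they are.
The ensemble probability is the weighted mean of the learners' class-1
probabilities.

`youden_threshold()` scans the unique observed scores as candidate
thresholds with the rule "positive iff score >= t" and maximises
J = sensitivity + specificity − 1; ties in J break toward the smallest
threshold, the more sensitive rule.

## Evaluation and comparison

`repeated_cv()` runs `n_rounds` (default 100) rounds of stratified
k-fold (default 10) cross-validation; fold assignment is shuffled
round-robin within each class. Each round pools its out-of-fold ensemble
scores, derives a Youden threshold **on those pooled scores** and computes
accuracy, precision, sensitivity, specificity and F1 at that threshold
(AUC is threshold-free). Deriving the threshold on the same scores it is
applied to is optimistic for the threshold-dependent metrics; the report
carries a note saying so. Under the null this machinery is honest: on
effect-free cohorts the mean cross-validated AUC sits near 0.5 (very
slightly below, the usual small pessimistic bias of out-of-fold prediction
on noise).

Summaries report the across-round mean with a 95% CI of the mean
(mean ± 1.96 sd/√n_rounds); the across-round sd and 2.5/97.5 percentiles
are emitted alongside so the round-distribution spread can be read
directly.

Between-model comparisons use two instruments: per-metric Welch t-tests on
the round-level values (unequal variances; round counts are equal but
variances need not be), and a Hanley–McNeil z-test on AUCs,
z = (A₁−A₂)/√(SE₁²+SE₂²), with SE from the closed form
SE² = [A(1−A) + (n⁺−1)(Q₁−A²) + (n⁻−1)(Q₂−A²)]/(n⁺n⁻),
Q₁ = A/(2−A), Q₂ = 2A²/(1+A). The independent-samples form is used — the
compared models are trained on different (sub)samples and no paired
correction is available — even though the pooled stratum contains the
gender strata's patients; the overlap is acknowledged in the comparison
log.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the pixel-level physics behind it. Its defaults describe a
CRLM-like cohort: 196 patients (117 male, 79 female), 59.7% expected
progression prevalence, and 1316 feature columns named by the taxonomy.

* **Correlated feature blocks.** Noise features are block-equicorrelated
  standard normals (block size 14, mirroring one block per base feature
  across the 14 image variants; within-block correlation 0.7). Radiomic
  features are notoriously redundant — image variants of the same base
  statistic are close surrogates — and treating the table as ~1300
  independent axes would be qualitatively wrong.
* **Gender-disjoint signal families.** Each gender has its own planted
  discriminative features (default 20 per gender) that fill whole blocks
  of their own, disjoint between genders by construction. Selected
  radiomic features arrive in correlated families in practice, and
  confining each gender's signal to its own families reproduces the
  disjoint-signature structure the stratified analysis is designed to
  detect. The planted shift (default 1.5 SD in the positive class of the
  matching gender) applies to signal features only; gender affects *which*
  features carry signal, never the marginal noise distribution.
* **Label-noise confounders.** After signal generation a simple-random
  fraction of patients (default 15%) have their label and DFS flipped
  while their features keep the pre-flip structure — the simplest
  mechanism for patients whose imaging contradicts their recorded
  outcome. DFS months are drawn consistent with the final label (at most
  36 for positives).

Missing values are rejected rather than imputed throughout: the feature
matrix contract is complete data, and clinical covariates (where
missingness is real) are handled separately by `compare_cohorts()` with
pairwise deletion and explicit missing counts.

What the generator does **not** emulate: real radiomic marginals (heavy
tails, mixed scales), nonlinear or interaction effects, scanner/site
batch structure, and — importantly — weak-signal regimes. With the default
planted effect, a 20-feature 1.5-SD family is strong: after the confounder
screen removes the worst-classified quartile, the retained synthetic
cohorts are almost perfectly classifiable and all three strata reach
cross-validated AUCs near 1. Passing tests on such cohorts demonstrate
that the machinery recovers planted structure (which features, which
patients, which gender) — they say nothing about the absolute performance
level to expect on real data, where per-feature effects are far weaker and
models land in the 0.6–0.8 AUC range. For the same reason the
stratified-versus-pooled AUC z-test, which has a clear signal in
weak-signal regimes, has little room to be significant between two models
that are both near ceiling.

## Numerical conventions

* Quantiles (confounder cutoff) use linear interpolation between order
  statistics (R type 7); flagging is strictly below the cutoff.
* Retention in selection is `frequency >= threshold`; significance is
  `p < alpha` (strict).
* Positive calls use `score >= threshold` everywhere.
* All stage seeds derive from one master seed by fixed offsets, so strata
  and stages are independently reproducible; re-running a configuration
  reproduces every report byte-for-byte.
* Degenerate cases are defined, not NaN: undefined metric ratios report 0
  with a warning; zero-variance t-tests return p = 1 (equal means) or 0
  (unequal); zero-SE AUC comparisons likewise.

## Problem sizes used by the test suite

The full defaults (500 selection rounds, 500 screening rounds, 100 CV
rounds) describe a production run. The package's tests and the
`scripts/acceptance.R` report use the `fast` preset (50/50/10) on the
default cohort and reduced cohorts (40–200 patients, 30–200 features) for
unit checks — sizes chosen so the whole suite exercises every stage at
study-like dimensions while remaining convenient to run routinely.
Power-style assertions (planted-feature recovery, flip recovery) were
calibrated at those sizes.

## Known limitations

* **Selection and screening leak into evaluation.** Features are selected
  and confounders removed on the same cohort that cross-validation then
  evaluates. Both steps bias performance upward: selected features carry
  in-sample association, and retained patients are those the same learner
  panel could classify. The framework reproduces this design faithfully
  rather than nesting the stages inside the CV loop; absolute performance
  numbers from `repeated_cv()` should be read accordingly.
* **The quartile screen is relative.** It removes ~25% of patients no
  matter how clean the data; it is a ranking device, not a noise test.
* **Null selection rate.** As discussed above, the selection procedure
  admits ~4–5% of noise features; selected sets from disjoint strata will
  usually share a few spurious members.
* **No multiple-testing correction, no nested tuning, no survival
  modelling** — these are outside the framework's scope by design.
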