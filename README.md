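# gendrad

Gender-stratified radiomic modelling of three-year disease progression in
resectable colorectal liver metastases (CRLM).

## What it does

Patients undergoing resection of colorectal liver metastases differ widely
in how soon disease returns, and growing evidence suggests that the
CT-imaging correlates of progression differ between men and women. gendrad
implements a reusable analysis framework for patient-by-feature radiomic
tables (PyRadiomics naming, 1316 features per patient) that runs the same
pipeline on three strata — all patients, men only, women only — and
statistically compares the resulting models. The outcome is binary:
progression within three years (disease-free survival ≤ 36 months).

Per stratum, the pipeline is:

1. **Stability feature selection.** Every feature is tested between outcome
   groups with a two-sided Wilcoxon/Mann–Whitney rank-sum test on 500
   class-stratified random subsamples of 80% of the patients; features
   significant (p < 0.05) in ≥ 40% of rounds are retained.
2. **Confounder screening.** Five classifiers (random forest, RBF-SVM, MLP,
   logistic regression, Gaussian naive Bayes) are trained on 500 stratified
   80% subsamples and score the held-out patients out-of-sample; patients
   whose mean correct-classification rate falls below the first quartile of
   the cohort distribution are flagged as confounders and removed.
3. **Ensemble evaluation.** An AUC-weighted soft-voting ensemble of the five
   classifiers — weights are inner 5-fold cross-validated AUCs normalised to
   sum to one, p(x) = Σₖ wₖ pₖ(x) — is evaluated over 100 rounds of
   stratified 10-fold cross-validation. Each round's pooled out-of-fold
   scores are thresholded at the Youden-index optimum
   (J = sensitivity + specificity − 1), and accuracy, precision,
   sensitivity, specificity, F1 and AUC are summarised as mean with 95% CI.

Across strata, the framework reports selected-feature overlap counts,
per-metric Welch t-tests on round-level values, and Hanley–McNeil z-tests
between AUCs, z = (A₁−A₂)/√(SE₁²+SE₂²) with
SE² = [A(1−A) + (n⁺−1)(Q₁−A²) + (n⁻−1)(Q₂−A²)]/(n⁺n⁻),
Q₁ = A/(2−A), Q₂ = 2A²/(1+A). Clinical-covariate comparability between
groups is tested with Pearson χ² (nominal) and rank-sum (interval) via
`compare_cohorts()`.

Because real DICOM processing is out of scope, the package ships a
first-class synthetic cohort generator that emulates the structure such
analyses assume: 117 male / 79 female patients, ~59.7% prevalence,
block-equicorrelated feature families, disjoint male- and female-specific
discriminative feature sets, and a planted fraction of label-noise
"confounder" patients. See the methods vignette
(`vignettes/gender-stratified-radiomics.Rmd`) for the generator's design,
the conventions of every stage, and known limitations.

## Worked example

```r
library(gendrad)
spec <- cohort_spec(n_male = 60, n_female = 40, n_features = 120,
                    n_signal_male = 8, n_signal_female = 8,
                    effect_size = 1.5, block_size = 8,
                    confounder_frac = 0.1, seed = 101)
cohort <- generate_cohort(spec)

sel <- select_features(cohort, selection_config(n_rounds = 50, seed = 1))
scr <- run_confounder_screen(cohort, sel$selected,
                             screen_config(n_rounds = 50, seed = 2))
ev  <- repeated_cv(scr$retained_table, sel$selected,
                   n_rounds = 5, k = 10, seed = 3)
```

This prints (abridged):

```
selected 14 of 120 features
male-signal features recovered: 8 of 8
flagged 25 patients; cutoff 0.338
flipped patients recovered: 5 of 10
       metric  mean ci_low ci_high
1    accuracy 0.960  0.960   0.960
2   precision 0.974  0.952   0.997
3 sensitivity 0.947  0.924   0.970
4 specificity 0.973  0.949   0.997
5          f1 0.960  0.959   0.961
6         auc 0.987  0.985   0.990
```

Reading the numbers: selection kept 14 features — all 16 planted signal
features minus misses plus a few borderline noise features (the procedure
admits ~4–5% of null features; see the vignette). The quartile screen
removed 25 of 100 patients, catching half of the 10 label-flipped ones in
this small cohort. The ensemble separates the retained patients nearly
perfectly — expected here, since the screen removes exactly the patients
the same learners cannot classify; absolute synthetic performance should
not be extrapolated to real data.

The full three-strata orchestration is one call:

```r
res <- run_framework(run_config(cohort_spec(seed = 1), fast = TRUE,
                                seed = 42, out_dir = "results/run1"))
res$comparisons$overlap   # selected-feature overlap between strata
res$comparisons$auc       # Hanley–McNeil z-tests vs the pooled model
```

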