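---
title: "Time-window prognostic models for MCI-to-dementia conversion: methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-window prognostic models: methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the two labeling designs

Cohorts of patients with mild cognitive impairment (MCI) mix people at very
different stages of the neurodegenerative process: some convert to dementia
within a year of baseline, others remain stable for a decade. The prevailing
way to build a prognostic classifier — label each patient by the diagnosis at
their *last* visit ("First-Last") — ignores this heterogeneity: a patient
converting after 9 years and one converting after 9 months both become
converters, although their baseline cognition is very different.

The time-window design asks a sharper clinical question: *will this patient
convert within k years?* For a window of k years:

* **cMCI** — dementia is observed at a follow-up visit strictly before k
  years (`boundary = "strict_paper"`; an `"inclusive"` dialect counts a
  diagnosis at exactly k). The class-defining time is the first dementia
  visit.
* **sMCI** — an MCI diagnosis is observed at or beyond k years; that visit
  proves the patient had not converted inside the window. The class-defining
  time is the earliest such visit.
* **discard** — the follow-up cannot decide the label: the patient is last
  seen (still MCI) before k years (`censored_before_window`), or dementia is
  first observed only at/after k years (`conversion_outside_window`) — the
  conversion may have happened on either side of the boundary. Patients
  without any follow-up are discarded under both designs.

Discarding is what distinguishes this from naive dichotomization of a
survival time: interval censoring is resolved by refusing to guess. Two
consequences are worth keeping in mind. First, the same patient can be sMCI
for a small window and cMCI for a larger one — that is clinically correct
behaviour, not leakage. Second, window labels are monotone: a converter
inside k stays a converter for every k' > k, and a patient stable at k' is
stable at every k < k'. `audit_monotonicity()` re-derives labels across a
window grid and reports violations; on valid histories it must return none.

A dementia diagnosis at *exactly* k years is ambiguous in prose ("within k
years"?). We default to the strict reading (conversion must be strictly
inside; an exact-boundary conversion discards as `conversion_outside_window`)
and expose the inclusive reading as a switch. Real visit times essentially
never hit the boundary; simulated grids can.

Features always come from the baseline assessment only. Follow-up
measurements are used solely to compute the class, never as predictors.

## Model selection protocol

`tw_train()` reproduces a leakage-free grid search:

* **Cross-validation**: stratified 5-fold CV repeated 10 times with fold
  re-randomization (`cv_plan()`, master seed 20170719 by default; repeat r
  uses seed + r, so all configurations see identical splits and their
  repeat-level metrics are paired).
* **In-fold preprocessing**: imputation, feature selection and SMOTE are
  fitted on the training fold only and applied to both sides of the split.
  The test fold influences nothing that is fitted — the test suite asserts
  this by mutating held-out rows and checking the fitted artifacts bit for
  bit.
* **Selection criterion**: mean area under the ROC curve, computed in
  Mann–Whitney form (ties credited 0.5). Sensitivity treats cMCI as the
  positive class. Headline mean ± sd aggregate the 10 repeat-level means;
  fold-level sds are also retained (sd over 50 folds is larger and answers a
  different question).
* **Classifier families** (delegated to established implementations behind a
  thin fit/score adapter): Naive Bayes (gaussian, supervised-discretization
  and kernel-density modes), decision tree (`rpart`), RBF and polynomial
  SVMs (`e1071`), k-nearest neighbours (`class`), random forest
  (`randomForest`) and ridge logistic regression (`glmnet`). Grid defaults
  (`default_grids()`): log-spaced scale parameters (SVM cost
  {0.1, 0.3, 1, 3, 10}, gamma {0.01, 0.1, 1, 10, 100}; ridge 1e-9..1e-6),
  exhaustive integer ranges where cheap (kNN 1..11, forest size 5..30, tree
  cp 0.05..0.5). The tree's pruning grid reuses the 0.05–0.5 range as
  `rpart`'s complexity parameter, the closest pruning knob in this
  implementation. Exact AUC ties go to the earlier configuration in
  canonical family/parameter order, making the search deterministic.

### Missing values

Numeric features are imputed with the training-fold mean, nominal ones with
the training-fold mode (ties to the lexicographically smallest token, for
determinism). Families that cannot score incomplete rows (SVMs, kNN, ridge
regression, random forest) are always imputed regardless of the MVI switch;
Naive Bayes and the tree can run on incomplete data, so for them the switch
is a real degree of freedom in the search.

### Feature selection (CFS)

Correlation-based feature selection scores a subset S of size s by

    merit(S) = s * mean(r_cf) / sqrt(s + s (s - 1) * mean(r_ff))

favouring features correlated with the class (r_cf) and penalizing mutual
redundancy (r_ff). Correlations are symmetrical uncertainties computed on
features discretized by supervised minimum-description-length (MDL) binning
fitted on the training rows — the canonical choice; a faster
absolute-Pearson-on-ranks mode is available (`fs_measure = "rank_pearson"`).
Constant features (and features MDL leaves unsplit) get correlation 0.
Missing cells form their own category in the contingency tables, so no rows
are dropped. The search is forward best-first, stopping after 5 consecutive
non-improving expansions, with ties broken by feature order. One caveat
observed while testing: with small samples the merit can *increase* when a
strong feature is duplicated (its class correlation exceeds the subset mean
by more than the denominator penalty); this is a property of the merit
itself, not of the search, and disappears at moderate sample sizes.

### Class imbalance (SMOTE)

SMOTE adds `floor(m * N / 100)` synthetic minority examples, each
interpolated uniformly between a minority seed row and one of its k = 5
nearest minority neighbours (Euclidean distance on numeric features);
nominal attributes are copied from the seed row. The searched percentages
run from 0 up to the *inversion* point

    N_inv = 100 * ((M / m)^2 - 1)

at which the post-SMOTE class proportions are exactly the original ones
swapped (derivation: m (1 + N/100) / (m (1 + N/100) + M) = M / (m + M)).
`smote_grid()` places 5 evenly spaced points on [0, min(N_inv, 2 N_bal)],
snapping one onto the exact-balance point N_bal = 100 (M/m - 1); 0 and
balance are always searched. In-fold, a requested percentage is capped at
that fold's own inversion bound. Within the grid search the selected subset
is re-fitted per training fold; `tw_finalize()` additionally fits one
pipeline (imputation, subset, SMOTE, classifier) on the full CV set for
validation and deployment — both per-fold and full-set selections are
reported because either convention is defensible.

## Statistical comparison

* `wilcoxon_signed_rank()` — paired two-sided test (e.g. feature selection
  on vs off per classifier), zeros dropped, midranks, exact null below 6
  non-zero differences.
* `friedman()` — rank test across ≥3 classifiers over paired blocks
  (repeats), with `bonferroni()` for the follow-up pairwise family.
* `mcnemar()` — paired correctness comparison through the discordant counts
  b and c; the reported statistic is always the continuity-corrected
  chi-square (|b−c|−1)²/(b+c), with an exact binomial p-value when b+c < 25.
* `compare_designs()` — McNemar between a window design and First-Last.
  Their example sets differ in membership (windows discard censored
  patients), so the comparison restricts to the patient intersection and
  uses each run's majority out-of-fold correctness over the 10 repeats.
  Note each design is scored against its *own* label definition; the test
  asks which design's predictions are right about its own question more
  often on the shared patients.

## The synthetic cohort generator

No public data accompany this problem, so the generator is a first-class
module with known ground truth, used by every test. It emulates a
memory-clinic MCI cohort:

* Baseline features: standard-normal numeric scores (20 by default, 5
  informative), optional nominal covariates; cells masked missing at 5%
  (MCAR by default; an MAR mode ties missingness to an observed covariate
  for leakage stress tests).
* Conversion times: accelerated-failure-time Weibull. Patient i converts at
  `T_i ~ Weibull(shape 1.4, scale 6.1 * exp(beta * sum(x_informative)))`, so
  worse (lower) scores mean earlier conversion. The shape 1.4 follows from
  the targeted growth of converter fractions across the 2–5 year windows
  (25 → 64%); the scale is the output of `calibrate_to_proportions()`
  against those targets; beta = 0.5 puts gaussian-Naive-Bayes CV AUC in the
  0.82–0.88 range typical of neuropsychological prognosis at these horizons.
* Visits: baseline at 0, then gaps Normal(1.15, 0.35) truncated at 0.25
  years, per-visit dropout 0.16, administrative horizon 11 years; follow-up
  ends at the first post-conversion visit (dementia is absorbing). These
  values reproduce follow-up of roughly 3.3 ± 2.8 years, with converters
  followed for less time than stable patients, as in real cohorts.

Two calibration helpers bisect on the baseline scale: to per-window cMCI
fractions (`calibrate_to_proportions()`, feasible only for targets
non-decreasing in k) and to the observed converter share
(`calibrate_to_converter_fraction()`). The two targets are mildly
inconsistent under a single scale — matching the window fractions puts the
observed converter share near 47% rather than ~36% — and the window
fractions win by default, since they define the learning task; the
converter-share calibration is available when the other regime is wanted.

What the generator does *not* emulate: real neuropsychological test
distributions and their intercorrelations, practice effects, measurement
error that varies with disease stage, informative (visit-timing) censoring
beyond dropout, and competing risks such as death. Passing tests therefore
demonstrate correctness of the machinery and qualitative behaviour
(windows beat First-Last; censoring is handled without leakage), not
clinical performance on any real cohort.

One qualitative finding deserves honesty: under this generator the
cross-validated AUC is essentially *flat* across the 2–5 year windows
(all ≈ 0.84–0.85, each far above First-Last ≈ 0.77). In the
accelerated-failure-time construction the feature–outcome link is
homoskedastic on the log-time scale, so the discriminability of "T < k"
barely depends on k; the window ordering observed in clinical reports
presumably reflects mechanisms listed above that this generator omits. The
acceptance suite states the strict non-decreasing check anyway, and it can
fail by a Monte-Carlo hair (gaps of ±0.002 against seed noise of ±0.02) —
the corresponding test documents the expected orderings rather than
tuning them away.

## Numerical and determinism choices

* All randomness flows from explicit seeds: the simulator requires one; the
  CV plan derives per-repeat seeds; SMOTE accepts one. Identical
  configuration + seed reproduces byte-identical output tables (asserted in
  the suite).
* Problem sizes in the test and acceptance runs — cohorts of 600 patients,
  10 seeds, the gaussian Naive Bayes reduced grid with SMOTE {0, balance} —
  keep a full qualitative replication cheap while leaving class counts
  (≈ 60–250 per class per window) large enough for stable fold metrics.
* Degenerate inputs: empty cohorts, all-missing features in a training
  fold, single-class folds, zero discordant pairs and all-zero paired
  differences all raise or warn explicitly rather than propagating NaNs;
  sensitivity/specificity report `NA` (not 0) when a class is absent.
* `run_all()` orchestrates the full comparison (First-Last + each window:
  build, search, optional independent validation, McNemar vs First-Last,
  Friedman across families) and writes a manifest with the configuration
  hash and seeds so any table can be regenerated.
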