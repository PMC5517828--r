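# mciwindows

Prognostic prediction of conversion from mild cognitive impairment (MCI) to
dementia, using **time windows**: instead of asking *"will this patient ever
convert?"* (the conventional First-Last design, which labels each patient by
the diagnosis at their last visit), each model answers *"will this patient
convert within k years of baseline?"* — a question clinicians can act on, and
one that trains classifiers on patients at comparable disease stages.

The package is aimed at biostatisticians and dementia researchers working
with longitudinal diagnosis histories plus baseline neuropsychological /
demographic features.

## What it does

**Censoring-aware example construction.** For a window of k years, each
patient history becomes:

- **cMCI** — dementia observed at a visit strictly before k years;
- **sMCI** — an MCI diagnosis observed at or beyond k years (the visit that
  proves the patient had not converted inside the window);
- **discarded**, with a logged reason, when follow-up cannot decide the
  label: still MCI but last seen before k years, or dementia first observed
  only at/after k years.

Labels are monotone in k (a cMCI at k stays cMCI for larger windows; an sMCI
at k is sMCI for smaller ones) and `audit_monotonicity()` verifies this on
any cohort.

**Leakage-free model selection.** `tw_train()` grid-searches seven
classifier families (Naive Bayes, decision tree, RBF/polynomial SVM, kNN,
random forest, ridge logistic regression) under stratified 5-fold
cross-validation repeated 10 times, maximizing the Mann–Whitney AUC.
Mean/mode imputation, correlation-based feature selection (CFS merit
`s·r̄_cf / sqrt(s + s(s−1)·r̄_ff)` with best-first search) and SMOTE
oversampling (percentages from 0 to the class-proportion inversion point
`100·((M/m)² − 1)`) are fitted inside each training fold only.

**Design comparison.** Wilcoxon signed-rank (preprocessing on/off), Friedman
plus Bonferroni-corrected pairwise tests (across classifiers), and McNemar on
paired out-of-fold correctness for Time-Windows vs First-Last
(`compare_designs()`).

**Synthetic cohorts with ground truth.** `simulate_cohort()` draws baseline
features, Weibull conversion times shifted by informative features (worse
scores → earlier conversion), jittered visit schedules, dropout and missing
cells; `calibrate_to_proportions()` tunes the hazard scale to target
per-window class fractions. All tests run against this generator — no
private data required.

## Worked example

```r
library(mciwindows)

sim <- simulate_cohort(sim_params(n_patients = 600), seed = 1)
summarize_cohort(sim$cohort)
#> <mci_cohort_summary> 600 patients
#>   follow-up 3.14 +/- 2.89 years; observed converters 44.8%; missing cells 4.8%
#>  design sMCI cMCI cMCI_frac discarded
#>      FL  242  269 0.5264188        89
#>      2y  270  108 0.2857143       222
#>      3y  191  158 0.4527221       251
#>      4y  149  195 0.5668605       256
#>      5y  109  218 0.6666667       273

es5 <- build_example_set(sim$cohort, "window", k = 5)
es5
#> <mci_example_set> design: window k=5y
#>   327 examples (109 sMCI, 218 cMCI), 273 discarded
#>               no_followup    censored_before_window conversion_outside_window
#>                        89                       162                        22

plan <- cv_plan()   # 10 x 5-fold stratified CV
search <- tw_train(es5, grids = list(nb = data.frame(mode = "gaussian")),
                   plan = plan, fs = FALSE, mvi = TRUE, smote_percents = 0)
search
#> <tw_search> design: window k=5y; 1 configuration(s) evaluated
#>   best: nb(mode=gaussian) fs=FALSE mvi=TRUE smote=0%
#>   AUC 0.894 +/- 0.008 | sens 0.892 | spec 0.674
```

So on this simulated cohort the 5-year-window Naive Bayes model separates
converters from stable patients with cross-validated AUC 0.894 ± 0.008
(mean ± sd over the 10 repeat means); sensitivity 0.89 means 89% of true
within-5-year converters are flagged. The same classifier under the
First-Last design reaches only AUC 0.805, and McNemar on the 327 shared
patients shows where the designs disagree:

```r
fl <- tw_train(build_example_set(sim$cohort, "first_last"),
               grids = list(nb = data.frame(mode = "gaussian")),
               plan = plan, fs = FALSE, mvi = TRUE, smote_percents = 0)
cmp <- compare_designs(search$best_cv, fl$best_cv)
cmp
#> <tw_comparison> mcnemar: statistic = 0.7347, p = 0.3914, n = 327
c(cmp$b, cmp$c)   # 5y-right/FL-wrong vs FL-right/5y-wrong
#> [1] 28 21

model <- tw_finalize(es5, search$best)   # frozen pipeline for new patients
predict(model, sim$cohort$features[3, -1])
#>   prob_cMCI  prob_sMCI predicted low_information
#> 3 0.9711254 0.02887459      cMCI           FALSE
```

`run_all()` wraps the whole protocol (First-Last + every window, grid search,
optional independent validation set, McNemar and Friedman reports, manifest);
`inst/cli/mciw.R` exposes `simulate`, `build-examples`, `audit`, `train` and
`compare` subcommands for shell use.

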