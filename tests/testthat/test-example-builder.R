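hist_df <- function(times, diags) {
  data.frame(time_years = times,
             diagnosis = factor(diags, levels = c("MCI", "DEMENTIA")))
}

test_that("summarize_history extracts conversion and last-MCI times", {
  s <- summarize_history(hist_df(c(0, 1, 3), c("MCI", "MCI", "DEMENTIA")))
  expect_equal(s$t_conv, 3)
  expect_equal(s$t_last_mci, 1)
  expect_true(s$has_followup)

  s <- summarize_history(hist_df(c(0, 4), c("MCI", "MCI")))
  expect_true(is.na(s$t_conv))
  expect_equal(s$t_last_mci, 4)

  s <- summarize_history(hist_df(0, "MCI"))
  expect_false(s$has_followup)
})

test_that("First-Last labels by the last evaluation's diagnosis", {
  out <- label_first_last(hist_df(c(0, 1, 3), c("MCI", "MCI", "DEMENTIA")))
  expect_equal(out$kind, "cMCI")
  expect_equal(out$class_defining_time, 3)

  out <- label_first_last(hist_df(c(0, 2), c("MCI", "MCI")))
  expect_equal(out$kind, "sMCI")
  expect_equal(out$class_defining_time, 2)

  out <- label_first_last(hist_df(0, "MCI"))
  expect_equal(out$kind, "discard")
  expect_equal(out$reason, "no_followup")
})

test_that("window labeling follows the censoring-aware rules", {
  cases <- list(
    # conversion strictly inside the window
    list(t = c(0, 1.1, 2.5), d = c("MCI", "MCI", "DEMENTIA"), k = 3,
         want = "cMCI", cdt = 2.5),
    # still MCI at or beyond the window
    list(t = c(0, 4.2), d = c("MCI", "MCI"), k = 3, want = "sMCI", cdt = 4.2),
    # censored: last seen MCI before the window closes
    list(t = c(0, 1.0), d = c("MCI", "MCI"), k = 2,
         want = "discard:censored_before_window"),
    # conversion first observed only outside the window
    list(t = c(0, 2.0, 6.0), d = c("MCI", "MCI", "DEMENTIA"), k = 5,
         want = "discard:conversion_outside_window"),
    # same patient flips sMCI -> cMCI as the window widens
    list(t = c(0, 5.5, 7.0), d = c("MCI", "MCI", "DEMENTIA"), k = 5,
         want = "sMCI", cdt = 5.5),
    list(t = c(0, 5.5, 7.0), d = c("MCI", "MCI", "DEMENTIA"), k = 8,
         want = "cMCI", cdt = 7.0))
  for (cs in cases) {
    out <- label_window(hist_df(cs$t, cs$d), cs$k)
    expect_equal(outcome_string(out), sub("^(cMCI|sMCI)$", "\\1", cs$want),
                 info = paste("k =", cs$k))
    if (!is.null(cs$cdt)) expect_equal(out$class_defining_time, cs$cdt)
  }
  expect_error(label_window(hist_df(c(0, 1), c("MCI", "MCI")), k = 0),
               "positive")
})

test_that("the boundary dialect decides a conversion at exactly k", {
  h <- hist_df(c(0, 3), c("MCI", "DEMENTIA"))
  expect_equal(label_window(h, 3, "strict_paper")$kind, "discard")
  expect_equal(label_window(h, 3, "strict_paper")$reason,
               "conversion_outside_window")
  expect_equal(label_window(h, 3, "inclusive")$kind, "cMCI")
  # an MCI visit at exactly k proves stability under both dialects
  h2 <- hist_df(c(0, 3), c("MCI", "MCI"))
  expect_equal(label_window(h2, 3, "strict_paper")$kind, "sMCI")
  expect_equal(label_window(h2, 3, "inclusive")$kind, "sMCI")
})

test_that("window labeling agrees with the brute-force oracle on random histories", {
  set.seed(424242)
  n_checked <- 0L
  for (i in seq_len(10000)) {
    h <- random_history()
    k <- sample(c(1, 2, 3, 4, 5, 2.05), 1)
    boundary <- sample(c("strict_paper", "inclusive"), 1)
    expect_identical(outcome_string(label_window(h, k, boundary)),
                     oracle_label_window(h, k, boundary))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 10000L)
})

test_that("the four canonical history patterns produce one of each outcome", {
  cohort <- four_pattern_cohort(k = 5)
  es <- build_example_set(cohort, "window", k = 5)
  expect_equal(nrow(es$examples), 2)
  expect_equal(nrow(es$discarded), 2)
  got <- setNames(as.character(es$examples$label), es$examples$patient_id)
  expect_equal(got[["A"]], "cMCI")
  expect_equal(got[["B"]], "sMCI")
  disc <- setNames(es$discarded$reason, es$discarded$patient_id)
  expect_equal(disc[["C"]], "censored_before_window")
  expect_equal(disc[["D"]], "conversion_outside_window")
})

test_that("every patient lands in exactly one of examples/discards, and FL never censors", {
  for (seed in 1:5) {
    sim <- simulate_cohort(sim_params(n_patients = 120), seed = seed)
    n <- length(unique(sim$cohort$visits$patient_id))
    for (spec in list(list("first_last", NULL), list("window", 2),
                      list("window", 5))) {
      es <- build_example_set(sim$cohort, spec[[1]], k = spec[[2]])
      expect_equal(nrow(es$examples) + nrow(es$discarded), n)
      expect_false(any(es$examples$patient_id %in% es$discarded$patient_id))
    }
    fl <- build_example_set(sim$cohort, "first_last")
    expect_true(all(fl$discarded$reason == "no_followup"))
  }
})

test_that("labels are monotone across windows and the audit finds no violations", {
  sim <- simulate_cohort(sim_params(n_patients = 300), seed = 9)
  report <- audit_monotonicity(sim$cohort, windows = c(2, 3, 4, 5))
  expect_equal(nrow(report), 0)
  labels <- attr(report, "labels")
  # cMCI monotone up, sMCI monotone down, FL consistency
  fl <- vapply(split_histories(sim$cohort), function(h) label_first_last(h)$kind,
               character(1))
  for (i in 1:3) {
    expect_true(all(labels[labels[, i] == "cMCI", i + 1] == "cMCI"))
    expect_true(all(labels[labels[, i + 1] == "sMCI", i] == "sMCI"))
  }
  expect_true(all(fl[labels[, 1] == "cMCI"] == "cMCI"))
  expect_true(all(labels[fl == "sMCI", 4] != "cMCI"))
})

test_that("example sets carry baseline features only and are order-deterministic", {
  sim <- simulate_cohort(sim_params(n_patients = 50), seed = 3)
  es1 <- build_example_set(sim$cohort, "window", k = 4)
  # shuffle patients in the input tables
  shuffled <- sim$cohort
  set.seed(1)
  perm <- sample(nrow(shuffled$visits))
  shuffled <- mci_cohort(shuffled$visits[perm, ],
                         shuffled$features[sample(nrow(shuffled$features)), ],
                         schema = shuffled$schema)
  es2 <- build_example_set(shuffled, "window", k = 4)
  expect_identical(es1$examples, es2$examples)
  expect_identical(es1$discarded, es2$discarded)
  feat_cols <- setdiff(names(es1$examples),
                       c("label", "class_defining_time", "patient_id"))
  expect_setequal(feat_cols, setdiff(names(sim$cohort$features), "patient_id"))
})
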