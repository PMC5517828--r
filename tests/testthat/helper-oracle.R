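# Independent brute-force oracle for window labeling: instead of the
# package's summary-then-rules path, scan every evaluation and classify the
# history by exhaustive case analysis over what was observed relative to k.
oracle_label_window <- function(evaluations, k, boundary = "strict_paper") {
  if (nrow(evaluations) < 2) return("discard:no_followup")
  saw_dem_inside <- FALSE
  saw_mci_at_or_after <- FALSE
  saw_dem_anywhere <- FALSE
  for (i in seq_len(nrow(evaluations))) {
    t <- evaluations$time_years[i]
    d <- as.character(evaluations$diagnosis[i])
    if (d == "DEMENTIA") {
      saw_dem_anywhere <- TRUE
      inside <- if (boundary == "strict_paper") t < k else t <= k
      if (inside) saw_dem_inside <- TRUE
    } else {
      if (t >= k) saw_mci_at_or_after <- TRUE
    }
  }
  if (saw_dem_inside) return("cMCI")
  if (saw_mci_at_or_after) return("sMCI")
  if (saw_dem_anywhere) return("discard:conversion_outside_window")
  "discard:censored_before_window"
}

outcome_string <- function(outcome) {
  if (outcome$kind == "discard") paste0("discard:", outcome$reason)
  else outcome$kind
}

# Random valid history: baseline MCI at 0, up to max_evals evaluations on a
# 0.1-year grid, optional conversion after which dementia is absorbing.
random_history <- function(max_evals = 6, max_time = 8) {
  n_extra <- sample(0:(max_evals - 1), 1)
  times <- 0
  if (n_extra > 0)
    times <- c(0, sort(sample(seq(1, max_time * 10), n_extra)) / 10)
  conv_at <- if (runif(1) < 0.5 && n_extra > 0)
    sample(2:length(times), 1) else Inf
  diagnosis <- ifelse(seq_along(times) >= conv_at, "DEMENTIA", "MCI")
  data.frame(time_years = times,
             diagnosis = factor(diagnosis, levels = c("MCI", "DEMENTIA")))
}

# Tiny four-patient cohort following the canonical A-D history patterns for
# a 5-year window: A converts inside, B stable beyond, C censored early,
# D converts only outside the window.
four_pattern_cohort <- function(k = 5) {
  visits <- rbind(
    data.frame(patient_id = "A", time_years = c(0, 1.1, 2.5),
               diagnosis = c("MCI", "MCI", "DEMENTIA")),
    data.frame(patient_id = "B", time_years = c(0, 3.0, k + 0.5),
               diagnosis = c("MCI", "MCI", "MCI")),
    data.frame(patient_id = "C", time_years = c(0, k - 1),
               diagnosis = c("MCI", "MCI")),
    data.frame(patient_id = "D", time_years = c(0, 2.0, k + 1.0),
               diagnosis = c("MCI", "MCI", "DEMENTIA")))
  mci_cohort(visits)
}
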