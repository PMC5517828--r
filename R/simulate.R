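#' Simulation parameters for a longitudinal MCI cohort
#'
#' Defaults emulate the regime of a memory-clinic MCI cohort: 719 patients,
#' follow-up around 3.3 +/- 2.8 years with roughly annual visits, about a
#' third of patients observed to convert, and window-dependent class
#' proportions rising from about a quarter converters at 2 years to about
#' two thirds at 5 years. Conversion times follow an accelerated-failure-time
#' Weibull model: informative baseline features shift the log scale, so worse
#' (lower) scores mean earlier conversion.
#'
#' @param n_patients cohort size.
#' @param n_numeric number of numeric (standardized test-score) features.
#' @param n_informative how many of them carry signal (the first ones).
#' @param beta per-informative-feature log-scale slope (AFT effect size).
#' @param shape,scale Weibull shape and baseline scale (years) of the
#'   conversion-time distribution.
#' @param visit_interval,visit_jitter mean and sd (years) of the gap between
#'   consecutive visits; gaps are truncated below at 0.25 years.
#' @param dropout per-visit probability that follow-up stops.
#' @param max_followup administrative censoring horizon (years).
#' @param missing_prob probability a feature cell is masked missing.
#' @param missing_mode \code{"mcar"} (default) or \code{"mar"} (missingness
#'   probability doubled where the first noise feature is positive; for
#'   leakage stress tests).
#' @param n_nominal number of nominal covariates (no signal; exercises mode
#'   imputation and SMOTE nominal handling).
#' @return List of class \code{sim_params}.
#' @export
sim_params <- function(n_patients = 719, n_numeric = 20, n_informative = 5,
                       beta = 0.5, shape = 1.4, scale = 6.1,
                       visit_interval = 1.15, visit_jitter = 0.35,
                       dropout = 0.16, max_followup = 11,
                       missing_prob = 0.05, missing_mode = c("mcar", "mar"),
                       n_nominal = 1) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_patients >= 1, n_numeric >= 1,
            n_informative >= 0, n_informative <= n_numeric,
            beta >= 0, shape > 0, scale > 0,
            visit_interval > 0, visit_jitter >= 0,
            dropout >= 0, dropout <= 1, max_followup > 0,
            missing_prob >= 0, missing_prob <= 1, n_nominal >= 0)
  structure(list(n_patients = n_patients, n_numeric = n_numeric,
                 n_informative = n_informative, beta = beta, shape = shape,
                 scale = scale, visit_interval = visit_interval,
                 visit_jitter = visit_jitter, dropout = dropout,
                 max_followup = max_followup, missing_prob = missing_prob,
                 missing_mode = missing_mode, n_nominal = n_nominal),
            class = "sim_params")
}

#' Simulate a longitudinal MCI cohort with known ground truth
#'
#' Numeric features are standard normal; the true conversion time of patient
#' i is Weibull with log-scale shifted by \code{beta} per unit of each
#' informative feature. Visits start at baseline (time 0, MCI by
#' construction) and recur at jittered intervals until dropout, the
#' administrative horizon, or the first visit at or after the true conversion
#' time, which is diagnosed DEMENTIA and ends follow-up (dementia is
#' absorbing). Feature cells are masked missing at the configured rate; the
#' diagnosis sequence is never masked.
#'
#' @param params a \code{\link{sim_params}}.
#' @param seed integer seed (mandatory: cohorts are reproducible by contract).
#' @return List with \code{cohort} (an \code{\link{mci_cohort}} with features)
#'   and \code{truth} (data frame: \code{patient_id}, \code{conv_time} -- the
#'   true, possibly unobserved conversion time -- plus attribute
#'   \code{"informative"} naming the signal features).
#' @export
simulate_cohort <- function(params = sim_params(), seed) {
  stopifnot(inherits(params, "sim_params"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- params$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  x <- matrix(rnorm(n * params$n_numeric), n, params$n_numeric,
              dimnames = list(NULL, sprintf("npt%02d", seq_len(params$n_numeric))))
  informative <- colnames(x)[seq_len(params$n_informative)]
  shift <- if (params$n_informative)
    x[, informative, drop = FALSE] %*% rep(params$beta, params$n_informative)
  else rep(0, n)
  conv_time <- rweibull(n, shape = params$shape,
                        scale = params$scale * exp(as.numeric(shift)))

  visits <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- 0
    repeat {
      t_last <- tm[length(tm)]
      if (t_last >= conv_time[i]) break        # demented: follow-up ends
      if (runif(1) < params$dropout) break     # lost to follow-up
      gap <- max(0.25, rnorm(1, params$visit_interval, params$visit_jitter))
      t_next <- t_last + gap
      if (t_next > params$max_followup) break  # administrative censoring
      tm <- c(tm, t_next)
    }
    visits[[i]] <- data.frame(
      patient_id = ids[i], time_years = tm,
      diagnosis = ifelse(tm >= conv_time[i], "DEMENTIA", "MCI"),
      stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visits)

  features <- as.data.frame(x)
  if (params$n_nominal > 0) {
    toks <- list(c("female", "male"), c("low", "mid", "high"))
    for (j in seq_len(params$n_nominal)) {
      tk <- toks[[((j - 1) %% 2) + 1]]
      features[[sprintf("nom%02d", j)]] <-
        factor(sample(tk, n, replace = TRUE), levels = tk)
    }
  }
  if (params$missing_prob > 0) {
    pm <- matrix(params$missing_prob, n, ncol(features))
    if (params$missing_mode == "mar" && params$n_informative < params$n_numeric) {
      driver <- x[, params$n_informative + 1]  # observed noise covariate
      pm[driver > 0, ] <- pmin(1, 2 * params$missing_prob)
      pm[, params$n_informative + 1] <- 0      # the driver itself stays observed
    }
    mask <- matrix(runif(n * ncol(features)) < pm, n)
    for (j in seq_len(ncol(features))) features[mask[, j], j] <- NA
  }
  features <- cbind(patient_id = ids, features, stringsAsFactors = FALSE)

  cohort <- mci_cohort(visits, features)
  truth <- data.frame(patient_id = ids, conv_time = conv_time,
                      stringsAsFactors = FALSE)
  attr(truth, "informative") <- informative
  list(cohort = cohort, truth = truth)
}

#' Calibrate the baseline hazard scale to target window class fractions
#'
#' Bisection on the Weibull baseline scale so that the simulated cMCI
#' fractions of the requested windows approximate the targets: larger scale
#' means later conversion and lower converter fractions, so the mean cMCI
#' fraction across windows is monotone in the scale and bisection applies.
#' Targets must be non-decreasing in window width (a larger window can only
#' add converters).
#'
#' @param targets named numeric vector of cMCI fractions (0..1), names are
#'   window widths in years, e.g. \code{c("2" = .25, "3" = .40, "4" = .53,
#'   "5" = .64)}.
#' @param params starting \code{\link{sim_params}}; only \code{scale} is
#'   adjusted.
#' @param n_sim cohort size used for the calibration simulations.
#' @param seed seed for the calibration simulations.
#' @param tol stop when the mean absolute gap between simulated and target
#'   mean fraction is below this.
#' @param max_iter bisection iterations.
#' @return \code{params} with the calibrated \code{scale}; the last simulated
#'   per-window fractions are attached as attribute \code{"achieved"}.
#' @export
calibrate_to_proportions <- function(targets, params = sim_params(),
                                     n_sim = 2000, seed = 1,
                                     tol = 0.005, max_iter = 25) {
  stopifnot(inherits(params, "sim_params"), length(targets) >= 1)
  windows <- as.numeric(names(targets))
  if (anyNA(windows)) stop("targets must be named by window width in years")
  o <- order(windows)
  windows <- windows[o]; targets <- as.numeric(targets)[o]
  if (any(targets < 0 | targets > 1)) stop("target fractions must be in [0, 1]")
  if (is.unsorted(targets))
    stop("infeasible targets: cMCI fractions must be non-decreasing in window width")

  sim_fracs <- function(scale) {
    p <- params; p$scale <- scale; p$n_patients <- n_sim
    cohort <- simulate_cohort(p, seed = seed)$cohort
    vapply(windows, function(k) {
      es <- build_example_set(cohort, "window", k = k)
      mean(es$examples$label == "cMCI")
    }, numeric(1))
  }
  target_mean <- mean(targets)
  lo <- 0.2; hi <- 60
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisect on log scale
    fr <- sim_fracs(mid)
    gap <- mean(fr) - target_mean
    if (abs(gap) < tol) break
    if (gap > 0) lo <- mid else hi <- mid  # too many converters: raise scale
  }
  params$scale <- mid
  achieved <- setNames(fr, paste0("k", windows))
  attr(params, "achieved") <- achieved
  dev <- abs(fr - targets)
  if (any(dev > 0.05))
    warning("calibrated fractions deviate more than 5 percentage points ",
            "from the targets at window(s): ",
            paste(windows[dev > 0.05], collapse = ", "))
  params
}

#' Calibrate the baseline scale to an observed converter fraction
#'
#' Bisection on the Weibull baseline scale so that the fraction of simulated
#' patients observed to convert during follow-up matches the target (e.g.
#' about a third of a memory-clinic MCI cohort over an 11-year horizon).
#'
#' @param target target fraction of patients with an observed dementia
#'   diagnosis, in (0, 1).
#' @inheritParams calibrate_to_proportions
#' @return \code{params} with the calibrated \code{scale}; the last simulated
#'   fraction is attached as attribute \code{"achieved"}.
#' @export
calibrate_to_converter_fraction <- function(target, params = sim_params(),
                                            n_sim = 2000, seed = 1,
                                            tol = 0.005, max_iter = 25) {
  stopifnot(inherits(params, "sim_params"), target > 0, target < 1)
  frac <- function(scale) {
    p <- params; p$scale <- scale; p$n_patients <- n_sim
    cohort <- simulate_cohort(p, seed = seed)$cohort
    mean(vapply(split_histories(cohort),
                function(h) any(h$diagnosis == "DEMENTIA"), logical(1)))
  }
  lo <- 0.2; hi <- 120
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    fr <- frac(mid)
    if (abs(fr - target) < tol) break
    if (fr > target) lo <- mid else hi <- mid
  }
  params$scale <- mid
  attr(params, "achieved") <- fr
  params
}

#' Demographic and class-proportion summary of a cohort
#'
#' Follow-up statistics, observed converter fraction, missingness rate and,
#' per requested window, the class counts and discard counts of the
#' corresponding example set (plus the First-Last design).
#'
#' @param cohort an \code{mci_cohort}.
#' @param windows window widths in years (may be empty: follow-up stats only).
#' @param boundary see \code{\link{label_window}}.
#' @return List of class \code{mci_cohort_summary}.
#' @export
summarize_cohort <- function(cohort, windows = c(2, 3, 4, 5),
                             boundary = "strict_paper") {
  stopifnot(inherits(cohort, "mci_cohort"))
  fu <- followup_times(cohort)
  histories <- split_histories(cohort)
  converted <- vapply(histories, function(h) any(h$diagnosis == "DEMENTIA"),
                      logical(1))
  miss_rate <- if (is.null(cohort$features)) NA_real_ else {
    fm <- cohort$features[setdiff(names(cohort$features), "patient_id")]
    mean(is.na(as.matrix(fm)))
  }
  per_design <- function(design, k = NULL) {
    es <- build_example_set(cohort, design, k = k, boundary = boundary)
    cnt <- table(es$examples$label)
    data.frame(design = if (design == "window") paste0(k, "y") else "FL",
               sMCI = cnt[["sMCI"]], cMCI = cnt[["cMCI"]],
               cMCI_frac = cnt[["cMCI"]] / sum(cnt),
               discarded = nrow(es$discarded), stringsAsFactors = FALSE)
  }
  designs <- c(list(per_design("first_last")),
               lapply(windows, function(k) per_design("window", k)))
  structure(list(n_patients = length(fu),
                 followup_mean = mean(fu), followup_sd = sd(fu),
                 converter_fraction = mean(converted),
                 missing_rate = miss_rate,
                 class_table = do.call(rbind, designs)),
            class = "mci_cohort_summary")
}

#' @export
print.mci_cohort_summary <- function(x, ...) {
  cat("<mci_cohort_summary> ", x$n_patients, " patients\n", sep = "")
  cat(sprintf("  follow-up %.2f +/- %.2f years; observed converters %.1f%%",
              x$followup_mean, x$followup_sd, 100 * x$converter_fraction))
  if (!is.na(x$missing_rate))
    cat(sprintf("; missing cells %.1f%%", 100 * x$missing_rate))
  cat("\n")
  print(x$class_table, row.names = FALSE)
  invisible(x)
}
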