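#' Repeated stratified cross-validation plan
#'
#' The model-selection protocol: a stratified \code{folds}-fold
#' cross-validation repeated \code{repeats} times with fold randomization.
#' Each repeat draws its folds from a seed derived as \code{seed + repeat},
#' so the splits are identical across classifier configurations (results are
#' paired) and across runs (results are reproducible).
#'
#' @param folds number of folds (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed master seed.
#' @return Object of class \code{tw_cv_plan}.
#' @export
cv_plan <- function(folds = 5, repeats = 10, seed = 20170719) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed)),
            class = "tw_cv_plan")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin starting at a random offset, so per-fold class proportions are
# within one example of the global proportions.
make_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (cl in levels(factor(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(folds, 1)
    assignment[idx] <- ((start + seq_along(idx) - 2L) %% folds) + 1L
  }
  assignment
}

# In-fold preprocessing: everything is fitted on the training rows only and
# then applied to both sides of the split.
preprocess_fold <- function(train, test, schema, config) {
  do_impute <- isTRUE(config$mvi) || needs_complete(config$classifier$family)
  if (do_impute) {
    im <- impute_fit(train, schema)
    train <- impute_apply(im, train)
    test <- impute_apply(im, test)
  }
  if (isTRUE(config$fs)) {
    fsub <- cfs_select(train[setdiff(names(train), META_COLS)], train$label,
                       measure = config$fs_measure %||% "mdl_su")
    keep <- if (length(fsub$features)) fsub$features
            else setdiff(names(train), META_COLS)  # degenerate: keep all
    train <- train[c(keep, intersect(META_COLS, names(train)))]
    test <- test[c(keep, intersect(META_COLS, names(test)))]
  }
  sp <- config$smote_percent %||% 0
  if (sp > 0) {
    counts <- table(train$label)
    cap <- max_smote_percent(min(counts), max(counts))
    train <- smote(train, min(sp, cap), k = config$smote_k %||% 5)
  }
  list(train = train, test = test)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run repeated stratified cross-validation for one configuration
#'
#' For every train/test split, imputation, CFS feature selection and SMOTE
#' are fitted on the training fold only (never on held-out rows), the
#' classifier is trained, and the held-out fold is scored. Metrics are
#' aggregated at the repeat level (each repeat's mean over its folds); the
#' headline mean/sd are computed over the repeat means. Per-patient
#' out-of-fold correctness (majority vote over repeats) is retained for the
#' McNemar design comparison.
#'
#' @param es an \code{mci_example_set}.
#' @param config list with \code{classifier} (a \code{\link{tw_classifier}}),
#'   and switches \code{fs}, \code{mvi} (logicals), \code{smote_percent}
#'   (percentage, capped in-fold at the inversion bound), optional
#'   \code{fs_measure} and \code{smote_k}.
#' @param plan a \code{\link{cv_plan}}.
#' @return Object of class \code{tw_cv}: \code{folds} (one row per split:
#'   repeat, fold, auc, sensitivity, specificity), \code{repeat_means},
#'   \code{mean_auc}, \code{sd_auc} (over repeat means), fold-level
#'   \code{sd_auc_folds}, and \code{oof} (per patient: mean out-of-fold
#'   score, proportion of repeats correct, majority correctness).
#' @export
run_cv <- function(es, config, plan = cv_plan()) {
  stopifnot(inherits(es, "mci_example_set"), inherits(plan, "tw_cv_plan"))
  data <- es$examples
  labels <- data$label
  counts <- table(labels)
  if (any(counts < plan$folds))
    stop("each class needs at least as many examples as folds (have ",
         paste(counts, collapse = "/"), ")")
  n <- nrow(data)
  schema <- es$schema %||% infer_schema(data[setdiff(names(data), META_COLS)])

  fold_rows <- vector("list", plan$repeats * plan$folds)
  score_mat <- matrix(NA_real_, n, plan$repeats)
  correct_mat <- matrix(NA, n, plan$repeats)

  for (r in seq_len(plan$repeats)) {
    set.seed(plan$seed + r)
    assignment <- make_folds(labels, plan$folds)
    for (f in seq_len(plan$folds)) {
      te <- assignment == f
      pp <- preprocess_fold(data[!te, , drop = FALSE],
                            data[te, , drop = FALSE], schema, config)
      fit <- fit_classifier(config$classifier, pp$train)
      sc <- predict_prob(fit, pp$test)
      pred <- ifelse(sc > 0.5, "cMCI", "sMCI")
      truth <- as.character(labels[te])
      ss <- sensitivity_specificity(pred, truth)
      a <- if (length(unique(truth)) == 2) auc_mw(sc, truth) else NA_real_
      fold_rows[[(r - 1) * plan$folds + f]] <- data.frame(
        repeat_ = r, fold = f, auc = a,
        sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]])
      score_mat[te, r] <- sc
      correct_mat[te, r] <- pred == truth
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  repeat_means <- aggregate(folds_df[c("auc", "sensitivity", "specificity")],
                            by = list(repeat_ = folds_df$repeat_),
                            FUN = mean, na.rm = TRUE)
  oof <- data.frame(
    patient_id = data$patient_id %||% as.character(seq_len(n)),
    label = labels,
    mean_score = rowMeans(score_mat),
    prop_correct = rowMeans(correct_mat),
    stringsAsFactors = FALSE)
  oof$correct <- oof$prop_correct >= 0.5
  structure(list(
    folds = folds_df,
    repeat_means = repeat_means,
    mean_auc = mean(repeat_means$auc),
    sd_auc = sd(repeat_means$auc),
    sd_auc_folds = sd(folds_df$auc, na.rm = TRUE),
    mean_sensitivity = mean(repeat_means$sensitivity, na.rm = TRUE),
    mean_specificity = mean(repeat_means$specificity, na.rm = TRUE),
    oof = oof, config = config, plan = plan), class = "tw_cv")
}

#' @export
print.tw_cv <- function(x, ...) {
  cat("<tw_cv> ", classifier_label(x$config$classifier),
      " | fs=", isTRUE(x$config$fs), " mvi=", isTRUE(x$config$mvi),
      " smote=", x$config$smote_percent %||% 0, "%\n", sep = "")
  cat(sprintf("  AUC %.3f +/- %.3f (over %d repeat means); sens %.3f spec %.3f\n",
              x$mean_auc, x$sd_auc, x$plan$repeats,
              x$mean_sensitivity, x$mean_specificity))
  invisible(x)
}
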