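#' Default classifier grids
#'
#' The discretized search space over the seven families: Naive Bayes mode
#' (gaussian / supervised discretization / kernel density); decision-tree
#' pruning \code{cp} over 0.05..0.5 step 0.05; RBF SVM cost
#' \{0.1, 0.3, 1, 3, 10\} x gamma \{0.01, 0.1, 1, 10, 100\}; polynomial SVM
#' cost x degree \{1, 2, 3\}; kNN neighbors 1..11; random-forest trees
#' \{5, 10, 15, 20, 25, 30\}; ridge logistic regression with ridge
#' \{1e-9, 1e-8, 1e-7, 1e-6\}. Scale parameters are log-spaced; integer
#' ranges are searched exhaustively.
#'
#' @param families subset of families to include (canonical order:
#'   \code{nb, dt, svm_rbf, svm_poly, knn, rf, lr}).
#' @return Named list of parameter-grid data frames, one per family.
#' @export
default_grids <- function(families = CLASSIFIER_FAMILIES) {
  families <- match.arg(families, CLASSIFIER_FAMILIES, several.ok = TRUE)
  all <- list(
    nb = data.frame(mode = c("gaussian", "supervised_discretization",
                             "kernel_density"), stringsAsFactors = FALSE),
    dt = data.frame(cp = seq(0.05, 0.5, by = 0.05)),
    svm_rbf = expand.grid(cost = c(0.1, 0.3, 1, 3, 10),
                          gamma = c(0.01, 0.1, 1, 10, 100)),
    svm_poly = expand.grid(cost = c(0.1, 0.3, 1, 3, 10), degree = 1:3),
    knn = data.frame(k = 1:11),
    rf = data.frame(iterations = c(5, 10, 15, 20, 25, 30)),
    lr = data.frame(ridge = c(1e-9, 1e-8, 1e-7, 1e-6)))
  all[intersect(CLASSIFIER_FAMILIES, families)]
}

# Expand grids x preprocessing switches into an ordered list of configs.
# Construction order is the deterministic tie-break of the search.
expand_configs <- function(grids, fs, mvi, smote_percents, fs_measure) {
  configs <- list()
  for (fam in names(grids)) {
    g <- grids[[fam]]
    for (i in seq_len(nrow(g))) {
      params <- as.list(g[i, , drop = FALSE])
      names(params) <- names(g)
      clf <- do.call(tw_classifier, c(list(family = fam), params))
      for (f in fs) for (m in mvi) for (sp in smote_percents) {
        configs[[length(configs) + 1]] <- list(
          classifier = clf, fs = f, mvi = m, smote_percent = sp,
          fs_measure = fs_measure)
      }
    }
  }
  configs
}

#' Grid search over classifiers and preprocessing under repeated CV
#'
#' Evaluates every configuration (classifier family x parameters x feature
#' selection on/off x imputation on/off x SMOTE percentage) with
#' \code{\link{run_cv}} and selects the configuration maximizing the mean AUC
#' over repeat means. All configurations share the same fold randomization, so
#' their repeat-level metrics are paired. Exact ties go to the configuration
#' earliest in the canonical family/parameter order.
#'
#' @param es an \code{mci_example_set}.
#' @param grids as \code{\link{default_grids}}.
#' @param plan a \code{\link{cv_plan}}.
#' @param fs,mvi logical vectors of switch values to search (e.g.
#'   \code{c(TRUE, FALSE)}).
#' @param smote_percents SMOTE percentages to search; \code{NULL} uses
#'   \code{\link{smote_grid}} on the example set's class counts.
#' @param fs_measure correlation measure for CFS (see \code{\link{cfs_merit}}).
#' @param keep_cv how many best configurations keep their full \code{tw_cv}
#'   object (the rest keep summary rows only, to bound memory).
#' @return Object of class \code{tw_search}: \code{best} (the winning
#'   config), \code{best_cv} (its \code{tw_cv}), \code{table} (one row per
#'   configuration with mean/sd metrics) and \code{cvs} (retained
#'   \code{tw_cv} objects, named by table row).
#' @export
tw_train <- function(es, grids = default_grids(), plan = cv_plan(),
                     fs = TRUE, mvi = TRUE, smote_percents = NULL,
                     fs_measure = "mdl_su", keep_cv = 1) {
  stopifnot(inherits(es, "mci_example_set"))
  if (is.null(smote_percents)) {
    counts <- table(es$examples$label)
    smote_percents <- smote_grid(min(counts), max(counts))
  }
  configs <- expand_configs(grids, fs, mvi, smote_percents, fs_measure)
  if (!length(configs)) stop("empty grid")

  rows <- vector("list", length(configs))
  cvs <- vector("list", length(configs))
  repeat_auc <- matrix(NA_real_, length(configs), plan$repeats)
  for (i in seq_along(configs)) {
    cv <- run_cv(es, configs[[i]], plan)
    repeat_auc[i, ] <- cv$repeat_means$auc
    rows[[i]] <- data.frame(
      config = i, family = configs[[i]]$classifier$family,
      params = classifier_label(configs[[i]]$classifier),
      fs = configs[[i]]$fs, mvi = configs[[i]]$mvi,
      smote_percent = configs[[i]]$smote_percent,
      mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
      sd_auc_folds = cv$sd_auc_folds,
      mean_sensitivity = cv$mean_sensitivity,
      mean_specificity = cv$mean_specificity,
      stringsAsFactors = FALSE)
    cvs[[i]] <- cv
  }
  tab <- do.call(rbind, rows)
  best_i <- which.max(tab$mean_auc)  # first max: canonical-order tie-break
  keep <- unique(c(best_i, order(-tab$mean_auc)[seq_len(min(keep_cv, nrow(tab)))]))
  cvs_kept <- cvs[keep]
  names(cvs_kept) <- as.character(keep)
  structure(list(design = es$design, k = es$k,
                 best = configs[[best_i]], best_index = best_i,
                 best_cv = cvs[[best_i]], table = tab, cvs = cvs_kept,
                 repeat_auc = repeat_auc, plan = plan),
            class = "tw_search")
}

#' @export
print.tw_search <- function(x, ...) {
  lbl <- if (x$design == "window") paste0("window k=", x$k, "y") else "first-last"
  cat("<tw_search> design: ", lbl, "; ", nrow(x$table),
      " configuration(s) evaluated\n", sep = "")
  cat("  best: ", classifier_label(x$best$classifier),
      " fs=", x$best$fs, " mvi=", x$best$mvi,
      " smote=", round(x$best$smote_percent, 1), "%\n", sep = "")
  cat(sprintf("  AUC %.3f +/- %.3f | sens %.3f | spec %.3f\n",
              x$best_cv$mean_auc, x$best_cv$sd_auc,
              x$best_cv$mean_sensitivity, x$best_cv$mean_specificity))
  invisible(x)
}

#' @export
summary.tw_search <- function(object, ...) {
  tab <- object$table[order(-object$table$mean_auc), ]
  rownames(tab) <- NULL
  tab
}

#' Fit the final prognostic pipeline on the full CV set
#'
#' Freezes the winning configuration: imputation model, CFS subset and SMOTE
#' are fitted once on the full cross-validation example set, the classifier is
#' trained on the preprocessed set, and the whole pipeline is returned as a
#' single predictor.
#'
#' @param es the cross-validation \code{mci_example_set}.
#' @param config a configuration as used by \code{\link{run_cv}} (e.g.
#'   \code{tw_search$best}).
#' @return Object of class \code{tw_model}.
#' @export
tw_finalize <- function(es, config) {
  stopifnot(inherits(es, "mci_example_set"))
  data <- es$examples
  schema <- es$schema %||% infer_schema(data[setdiff(names(data), META_COLS)])
  impute_model <- NULL
  if (isTRUE(config$mvi) || needs_complete(config$classifier$family)) {
    impute_model <- impute_fit(data, schema)
    data <- impute_apply(impute_model, data)
  }
  subset <- NULL
  if (isTRUE(config$fs)) {
    fsub <- cfs_select(data[setdiff(names(data), META_COLS)], data$label,
                       measure = config$fs_measure %||% "mdl_su")
    if (length(fsub$features)) {
      subset <- fsub
      data <- data[c(fsub$features, intersect(META_COLS, names(data)))]
    }
  }
  sp <- config$smote_percent %||% 0
  if (sp > 0) {
    counts <- table(data$label)
    data <- smote(data, min(sp, max_smote_percent(min(counts), max(counts))),
                  k = config$smote_k %||% 5)
  }
  fit <- fit_classifier(config$classifier, data)
  structure(list(design = es$design, k = es$k, config = config,
                 schema = schema, impute_model = impute_model,
                 subset = subset, fit = fit,
                 cv_patients = unique(es$examples$patient_id)),
            class = "tw_model")
}

#' @export
print.tw_model <- function(x, ...) {
  lbl <- if (x$design == "window") paste0("window k=", x$k, "y") else "first-last"
  cat("<tw_model> design: ", lbl, "; classifier ",
      classifier_label(x$config$classifier), "\n", sep = "")
  if (!is.null(x$subset))
    cat("  ", length(x$subset$features), " selected feature(s)\n", sep = "")
  invisible(x)
}

#' Predict conversion probability for new baseline feature rows
#'
#' Applies the frozen pipeline (imputation model, feature subset, classifier)
#' to new patients. Rows that were entirely missing before imputation are
#' flagged low-information: their prediction rests on fill values alone.
#'
#' @param object a \code{tw_model}.
#' @param newdata data frame of baseline features (schema columns).
#' @param ... unused.
#' @return Data frame with \code{prob_cMCI}, \code{prob_sMCI},
#'   \code{predicted} and \code{low_information}.
#' @export
predict.tw_model <- function(object, newdata, ...) {
  feats <- intersect(schema_features(object$schema), names(newdata))
  if (!length(feats)) stop("newdata shares no feature with the model schema")
  all_missing <- apply(is.na(newdata[feats]), 1, all)
  if (!is.null(object$impute_model))
    newdata <- impute_apply(object$impute_model, newdata)
  p <- predict_prob(object$fit, newdata)
  data.frame(prob_cMCI = p, prob_sMCI = 1 - p,
             predicted = factor(ifelse(p > 0.5, "cMCI", "sMCI"),
                                levels = LABEL_LEVELS),
             low_information = all_missing)
}

#' Validate a finalized model on an independent example set
#'
#' The validation set must be built under the same design (same window k or
#' First-Last) and share no patient with the CV set (leakage guard). The
#' frozen pipeline is applied and AUC / sensitivity / specificity are
#' returned.
#'
#' @param cv_es cross-validation \code{mci_example_set}.
#' @param val_es validation \code{mci_example_set}.
#' @param config configuration to finalize (e.g. \code{tw_search$best}).
#' @return List with \code{model} (the \code{tw_model}) and \code{metrics}
#'   (auc, sensitivity, specificity, n).
#' @export
finalize_and_validate <- function(cv_es, val_es, config) {
  stopifnot(inherits(cv_es, "mci_example_set"),
            inherits(val_es, "mci_example_set"))
  if (!identical(cv_es$design, val_es$design) ||
      !identical(cv_es$k, val_es$k))
    stop("validation set must be built with the same design as the CV set")
  overlap <- intersect(cv_es$examples$patient_id, val_es$examples$patient_id)
  if (length(overlap))
    stop("overlapping patient id(s) between CV and validation sets: ",
         paste(head(overlap, 5), collapse = ", "))
  model <- tw_finalize(cv_es, config)
  pred <- predict(model, val_es$examples)
  truth <- as.character(val_es$examples$label)
  ss <- sensitivity_specificity(pred$predicted, truth)
  list(model = model,
       metrics = list(auc = auc_mw(pred$prob_cMCI, truth),
                      sensitivity = ss[["sensitivity"]],
                      specificity = ss[["specificity"]],
                      n = nrow(val_es$examples)))
}
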