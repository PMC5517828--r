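#' Configuration for a full Time-Windows vs First-Last run
#'
#' @param windows window widths in years (positive, sorted).
#' @param include_first_last evaluate the First-Last design too (needed for
#'   the McNemar design comparison).
#' @param boundary window boundary dialect (see \code{\link{label_window}}).
#' @param grids classifier grids (see \code{\link{default_grids}}).
#' @param plan a \code{\link{cv_plan}}.
#' @param fs,mvi,smote_percents,fs_measure search switches passed to
#'   \code{\link{tw_train}}.
#' @param validation_cohort optional independent \code{mci_cohort} for
#'   \code{\link{finalize_and_validate}}; its patient ids must be disjoint
#'   from the CV cohort's.
#' @return List of class \code{tw_run_config}.
#' @export
run_config <- function(windows = c(2, 3, 4, 5), include_first_last = TRUE,
                       boundary = "strict_paper", grids = default_grids(),
                       plan = cv_plan(), fs = TRUE, mvi = TRUE,
                       smote_percents = NULL, fs_measure = "mdl_su",
                       validation_cohort = NULL) {
  if (length(windows) && (any(windows <= 0) || is.unsorted(windows, strictly = TRUE)))
    stop("windows must be positive and strictly increasing")
  structure(list(windows = windows, include_first_last = include_first_last,
                 boundary = boundary, grids = grids, plan = plan, fs = fs,
                 mvi = mvi, smote_percents = smote_percents,
                 fs_measure = fs_measure,
                 validation_cohort = validation_cohort),
            class = "tw_run_config")
}

design_key <- function(design, k) if (design == "window") paste0(k, "y") else "FL"

#' Run the full pipeline: build examples, learn, validate, compare
#'
#' For the First-Last design and each window: builds the example set (with
#' discard log), grid-searches classifiers under the CV plan, and -- when a
#' validation cohort is configured -- finalizes the best pipeline on the CV
#' set and scores the independent set. Designs are then compared: McNemar of
#' each window against First-Last on the shared patients, and a Friedman test
#' across classifier families per design when at least three families were
#' searched.
#'
#' @param cohort the cross-validation \code{mci_cohort} (visits + features).
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional directory; when given, example sets, grid tables,
#'   per-fold results and comparison tables are written there as CSV along
#'   with a manifest of the configuration.
#' @return Object of class \code{tw_run}: \code{example_sets},
#'   \code{searches} (named "FL", "2y", ...), \code{validation},
#'   \code{mcnemar_vs_fl}, \code{friedman_by_design}, \code{manifest}.
#' @export
run_all <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "mci_cohort"), inherits(config, "tw_run_config"))
  if (!is.null(config$validation_cohort)) {
    overlap <- intersect(patient_ids(cohort),
                         patient_ids(config$validation_cohort))
    if (length(overlap))
      stop("validation cohort shares patient id(s) with the CV cohort")
  }
  designs <- list()
  if (config$include_first_last)
    designs[["FL"]] <- list(design = "first_last", k = NULL)
  for (k in config$windows)
    designs[[design_key("window", k)]] <- list(design = "window", k = k)
  if (!length(designs)) stop("nothing to run: no designs configured")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }

  example_sets <- searches <- validation <- list()
  for (nm in names(designs)) {
    d <- designs[[nm]]
    example_sets[[nm]] <- stage(paste0("build-examples ", nm),
      build_example_set(cohort, d$design, k = d$k, boundary = config$boundary))
    searches[[nm]] <- stage(paste0("train ", nm),
      tw_train(example_sets[[nm]], grids = config$grids, plan = config$plan,
               fs = config$fs, mvi = config$mvi,
               smote_percents = config$smote_percents,
               fs_measure = config$fs_measure))
    if (!is.null(config$validation_cohort)) {
      val_es <- stage(paste0("build-validation ", nm),
        build_example_set(config$validation_cohort, d$design, k = d$k,
                          boundary = config$boundary))
      validation[[nm]] <- stage(paste0("validate ", nm),
        finalize_and_validate(example_sets[[nm]], val_es,
                              searches[[nm]]$best))
    }
  }

  mcnemar_vs_fl <- list()
  if (config$include_first_last && length(config$windows)) {
    for (k in config$windows) {
      nm <- design_key("window", k)
      mcnemar_vs_fl[[nm]] <- stage(paste0("compare ", nm, " vs FL"),
        compare_designs(searches[[nm]]$best_cv, searches[["FL"]]$best_cv))
    }
  }

  friedman_by_design <- list()
  fams <- names(config$grids)
  if (length(fams) >= 3) {
    for (nm in names(searches)) {
      tab <- searches[[nm]]$table
      best_rows <- vapply(fams, function(f) {
        rows <- which(tab$family == f)
        rows[which.max(tab$mean_auc[rows])]
      }, integer(1))
      mat <- searches[[nm]]$repeat_auc[best_rows, , drop = FALSE]
      rownames(mat) <- fams
      friedman_by_design[[nm]] <- friedman(mat)
    }
  }

  manifest <- list(
    designs = names(designs), seed = config$plan$seed,
    folds = config$plan$folds, repeats = config$plan$repeats,
    boundary = config$boundary,
    families = fams,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  run <- structure(list(example_sets = example_sets, searches = searches,
                        validation = validation,
                        mcnemar_vs_fl = mcnemar_vs_fl,
                        friedman_by_design = friedman_by_design,
                        manifest = manifest),
                   class = "tw_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

config_hash <- function(config) {
  config$validation_cohort <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[sort(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$example_sets))
    write_example_set(run$example_sets[[nm]],
                      file.path(out_dir, paste0("examples_", nm, ".csv")))
  grid_tabs <- do.call(rbind, lapply(names(run$searches), function(nm)
    cbind(design = nm, run$searches[[nm]]$table)))
  write.csv(grid_tabs, file.path(out_dir, "grid_table.csv"), row.names = FALSE)
  fold_tabs <- do.call(rbind, lapply(names(run$searches), function(nm)
    cbind(design = nm, run$searches[[nm]]$best_cv$folds)))
  write.csv(fold_tabs, file.path(out_dir, "best_fold_results.csv"),
            row.names = FALSE)
  if (length(run$mcnemar_vs_fl)) {
    cmp <- do.call(rbind, lapply(names(run$mcnemar_vs_fl), function(nm) {
      m <- run$mcnemar_vs_fl[[nm]]
      data.frame(window = nm, statistic = m$statistic, p_value = m$p_value,
                 b = m$b, c = m$c, n = m$n)
    }))
    write.csv(cmp, file.path(out_dir, "mcnemar_vs_fl.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.tw_run <- function(x, ...) {
  cat("<tw_run> designs: ", paste(x$manifest$designs, collapse = ", "),
      " (seed ", x$manifest$seed, ")\n", sep = "")
  for (nm in names(x$searches)) {
    s <- x$searches[[nm]]
    cat(sprintf("  %-3s best %-28s AUC %.3f +/- %.3f", nm,
                classifier_label(s$best$classifier),
                s$best_cv$mean_auc, s$best_cv$sd_auc))
    if (!is.null(x$validation[[nm]]))
      cat(sprintf(" | validation AUC %.3f", x$validation[[nm]]$metrics$auc))
    if (!is.null(x$mcnemar_vs_fl[[nm]])) {
      m <- x$mcnemar_vs_fl[[nm]]
      cat(sprintf(" | vs FL: b=%d c=%d p=%.3g", m$b, m$c, m$p_value))
    }
    cat("\n")
  }
  invisible(x)
}

#' Predict prognosis for new MCI patients
#'
#' Thin wrapper over \code{predict.tw_model} for new baseline feature rows;
#' returns the probability of conversion within the model's window.
#'
#' @param model a \code{tw_model}.
#' @param new_features data frame of baseline features for new patients.
#' @return See \code{\link{predict.tw_model}}.
#' @export
predict_new <- function(model, new_features) {
  stopifnot(inherits(model, "tw_model"))
  predict(model, new_features)
}
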