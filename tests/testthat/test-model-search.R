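test_that("Mann-Whitney AUC counts pairs and credits ties 0.5", {
  # perfect separation
  expect_equal(auc_mw(c(0.9, 0.8, 0.3, 0.2),
                      c("cMCI", "cMCI", "sMCI", "sMCI")), 1.0)
  # one tied positive-negative pair: (1 + 1 + 0.5 + 1) / 4
  expect_equal(auc_mw(c(0.7, 0.5, 0.5, 0.1),
                      c("cMCI", "cMCI", "sMCI", "sMCI")), 0.875)
  # chance level for labels independent of scores
  set.seed(10)
  sc <- runif(4000)
  lab <- sample(c("cMCI", "sMCI"), 4000, replace = TRUE)
  expect_lt(abs(auc_mw(sc, lab) - 0.5), 0.03)
  expect_error(auc_mw(c(1, 2), c("cMCI", "cMCI")), "both classes")

  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(11)
  sc <- rnorm(200); lab <- ifelse(rnorm(200, sc) > 0, "cMCI", "sMCI")
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, sc,
    levels = c("sMCI", "cMCI"), direction = "<"))))
  expect_equal(auc_mw(sc, lab), ref, tolerance = 1e-12)
})

test_that("sensitivity counts converters, specificity stable patients", {
  expect_equal(sensitivity_specificity(c("cMCI", "sMCI"), c("cMCI", "sMCI")),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(rep("sMCI", 4),
                                       c("cMCI", "cMCI", "sMCI", "sMCI")),
               c(sensitivity = 0, specificity = 1))
  # TP=8 FN=2 TN=6 FP=4
  truth <- c(rep("cMCI", 10), rep("sMCI", 10))
  pred <- c(rep("cMCI", 8), rep("sMCI", 2), rep("cMCI", 4), rep("sMCI", 6))
  expect_equal(sensitivity_specificity(pred, truth),
               c(sensitivity = 0.8, specificity = 0.6))
  # absent class reports NA, not 0
  ss <- sensitivity_specificity(c("sMCI", "sMCI"), c("sMCI", "sMCI"))
  expect_true(is.na(ss[["sensitivity"]]))
  expect_equal(ss[["specificity"]], 1)
})

test_that("every classifier family fits and scores probabilities in [0,1]", {
  df <- separable_examples(n = 60, seed = 21)
  df$nom <- factor(rep(c("x", "y"), 30))
  configs <- list(
    tw_classifier("nb", mode = "gaussian"),
    tw_classifier("nb", mode = "supervised_discretization"),
    tw_classifier("nb", mode = "kernel_density"),
    tw_classifier("dt", cp = 0.1),
    tw_classifier("svm_rbf", cost = 1, gamma = 0.1),
    tw_classifier("svm_poly", cost = 1, degree = 2),
    tw_classifier("knn", k = 3),
    tw_classifier("rf", iterations = 10),
    tw_classifier("lr", ridge = 1e-8))
  for (clf in configs) {
    set.seed(1)
    fit <- fit_classifier(clf, df)
    p <- predict_prob(fit, df)
    expect_true(all(p >= 0 & p <= 1), info = clf$family)
    # separable blobs: essentially perfect ranking for every family
    expect_gt(auc_mw(p, df$label), 0.95)
  }
  expect_error(tw_classifier("nb", neighbors = 3), "unknown parameter")
})

test_that("run_cv is deterministic, leak-free and covers each example once per repeat", {
  es <- as_example_set(planted_signal_examples(n = 100, seed = 31))
  plan <- cv_plan(folds = 5, repeats = 3, seed = 77)
  cv1 <- run_cv(es, fast_nb_config(), plan)
  cv2 <- run_cv(es, fast_nb_config(), plan)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$oof, cv2$oof)
  expect_equal(nrow(cv1$folds), 15)
  # out-of-fold coverage: no NA anywhere in the per-repeat score matrix
  expect_false(anyNA(cv1$oof$mean_score))
  expect_false(anyNA(cv1$oof$prop_correct))
  # aggregation: headline mean is the mean of repeat means
  expect_equal(cv1$mean_auc, mean(cv1$repeat_means$auc))
})

test_that("run_cv reaches AUC 1 on separable data and chance on permuted labels", {
  es <- as_example_set(separable_examples(n = 80, seed = 41))
  cv <- run_cv(es, fast_nb_config(), cv_plan(repeats = 2, seed = 5))
  expect_equal(cv$mean_auc, 1.0)
  expect_equal(cv$sd_auc, 0.0)

  df <- planted_signal_examples(n = 500, seed = 42)
  set.seed(99)
  df$label <- sample(df$label)   # break the signal
  cvp <- run_cv(as_example_set(df), fast_nb_config(),
                cv_plan(repeats = 2, seed = 5))
  expect_lt(abs(cvp$mean_auc - 0.5), 0.05)

  tiny <- planted_signal_examples(n = 9, seed = 1)  # 4 sMCI < 5 folds
  expect_error(run_cv(as_example_set(tiny), fast_nb_config(),
                      cv_plan(folds = 5)), "at least as many examples")
})

test_that("stratified folds keep class proportions within one example", {
  df <- planted_signal_examples(n = 103, seed = 51)
  df$label <- factor(rep(c("sMCI", "cMCI"), c(70, 33))[sample(103)],
                     levels = c("sMCI", "cMCI"))
  set.seed(3)
  for (i in 1:10) {
    fold <- mciwindows:::make_folds(df$label, 5)
    per_fold <- table(fold, df$label)
    expect_true(all(abs(per_fold[, "cMCI"] - 33 / 5) < 1))
    expect_true(all(abs(per_fold[, "sMCI"] - 70 / 5) < 1))
  }
})

test_that("grid search maximizes mean AUC with a canonical-order tie-break", {
  es <- as_example_set(planted_signal_examples(n = 100, seed = 61))
  plan <- cv_plan(repeats = 2, seed = 13)

  # single-configuration grid returns that configuration
  g1 <- tw_train(es, grids = list(knn = data.frame(k = 5)), plan = plan,
                 fs = FALSE, mvi = TRUE, smote_percents = 0)
  expect_equal(g1$best$classifier$family, "knn")
  expect_equal(g1$best$classifier$params$k, 5)

  # best mean AUC is an argmax over the table
  g2 <- tw_train(es, grids = list(nb = data.frame(mode = "gaussian"),
                                  knn = data.frame(k = c(1, 7))),
                 plan = plan, fs = FALSE, mvi = TRUE, smote_percents = 0)
  expect_equal(max(g2$table$mean_auc), g2$best_cv$mean_auc)
  expect_true(all(g2$best_cv$mean_auc >= g2$table$mean_auc))

  # identical configurations tie -> the earlier (canonical order) wins
  g3 <- tw_train(es, grids = list(nb = data.frame(mode = c("gaussian",
                                                           "gaussian"))),
                 plan = plan, fs = FALSE, mvi = TRUE, smote_percents = 0)
  expect_equal(g3$best_index, 1L)
  expect_error(tw_train(es, grids = list(), plan = plan), "empty grid")
})

test_that("a feature-using configuration beats a feature-blind control", {
  df <- planted_signal_examples(n = 120, n_informative = 3, n_noise = 3,
                                seed = 71)
  es <- as_example_set(df)
  plan <- cv_plan(repeats = 2, seed = 17)
  informed <- run_cv(es, fast_nb_config(), plan)
  blind_df <- df
  blind_df[grep("^inf", names(df))] <- NULL
  set.seed(1)
  blind_df$label <- sample(blind_df$label)  # control: no usable signal
  blind <- run_cv(as_example_set(blind_df), fast_nb_config(), plan)
  expect_gt(informed$mean_auc, blind$mean_auc)
})

test_that("finalize_and_validate freezes the pipeline and guards leakage", {
  cv_df <- planted_signal_examples(n = 120, seed = 81)
  val_df <- planted_signal_examples(n = 60, seed = 82)
  val_df$patient_id <- sprintf("V%03d", seq_len(nrow(val_df)))
  cv_es <- as_example_set(cv_df)
  val_es <- as_example_set(val_df)
  config <- fast_nb_config(fs = TRUE)
  cv <- run_cv(cv_es, config, cv_plan(repeats = 2, seed = 19))
  out <- finalize_and_validate(cv_es, val_es, config)
  # i.i.d. validation data with strong signal: AUC within 0.1 of CV AUC
  expect_lt(abs(out$metrics$auc - cv$mean_auc), 0.1)

  # label-permuted validation set scores at chance
  val_perm <- val_es
  set.seed(4)
  val_perm$examples$label <- sample(val_perm$examples$label)
  out_perm <- finalize_and_validate(cv_es, val_perm, config)
  expect_lt(abs(out_perm$metrics$auc - 0.5), 0.15)

  # overlapping patient ids are rejected
  val_bad <- val_es
  val_bad$examples$patient_id[1] <- cv_df$patient_id[1]
  expect_error(finalize_and_validate(cv_es, val_bad, config), "overlapping")
  # design mismatch is rejected
  fl_es <- val_es; fl_es$design <- "first_last"; fl_es$k <- NULL
  expect_error(finalize_and_validate(cv_es, fl_es, config), "same design")
})

test_that("predict.tw_model returns normalized probabilities and flags empty rows", {
  df <- planted_signal_examples(n = 80, seed = 91)
  es <- as_example_set(df)
  model <- tw_finalize(es, fast_nb_config())
  new_rows <- df[1:3, setdiff(names(df), c("label", "class_defining_time",
                                           "patient_id"))]
  new_rows[3, ] <- NA
  pred <- predict(model, new_rows)
  expect_equal(pred$prob_cMCI + pred$prob_sMCI, rep(1, 3))
  expect_true(all(pred$prob_cMCI >= 0 & pred$prob_cMCI <= 1))
  expect_equal(pred$low_information, c(FALSE, FALSE, TRUE))
  # a confidently-classified training row keeps its side of 0.5
  expect_equal(as.character(pred$predicted[1]), as.character(df$label[1]))
})
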