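test_that("imputation fills with training mean / lexicographic-min mode", {
  train <- data.frame(num = c(1, 3, NA),
                      nom = factor(c("a", "a", "b"), levels = c("a", "b")))
  m <- impute_fit(train)
  expect_equal(m$fills$num, 2)
  expect_equal(m$fills$nom, "a")
  filled <- impute_apply(m, train)
  expect_equal(filled$num, c(1, 3, 2))

  # mode tie breaks to the smallest token
  tie <- data.frame(nom = factor(c("b", "a"), levels = c("a", "b", "c")))
  expect_equal(impute_fit(tie)$fills$nom, "a")

  # all-missing feature is a hard error
  expect_error(impute_fit(data.frame(num = c(NA_real_, NA_real_))),
               "entirely missing")
})

test_that("imputation is identity on complete data and only touches missing cells", {
  set.seed(2)
  df <- data.frame(a = rnorm(10), b = rnorm(10))
  m <- impute_fit(df)
  expect_identical(impute_apply(m, df), df)

  df2 <- df
  df2$a[c(2, 5)] <- NA
  filled <- impute_apply(impute_fit(df2), df2)
  expect_equal(filled$a[-c(2, 5)], df$a[-c(2, 5)])
  expect_equal(filled$b, df$b)
  # fills are identifiable: re-deleting the mask recovers the original
  refilled <- filled
  refilled$a[c(2, 5)] <- NA
  expect_equal(refilled, df2)
})

test_that("held-out rows never influence fitted preprocessing (leakage suite)", {
  set.seed(7)
  train <- planted_signal_examples(n = 80, seed = 11)
  train$inf01[c(3, 9)] <- NA
  test <- planted_signal_examples(n = 20, seed = 12)
  feat <- function(df) df[setdiff(names(df), c("label", "class_defining_time",
                                               "patient_id"))]

  # run the full in-fold pipeline against original and mutated held-out rows:
  # everything fitted (imputation fills, selected subset, SMOTE rows) and the
  # preprocessed training fold must be identical
  schema <- infer_schema(feat(train))
  config <- list(classifier = tw_classifier("nb"), fs = TRUE, mvi = TRUE,
                 smote_percent = 50)
  test_mut <- test
  test_mut[, 1:5] <- test_mut[, 1:5] + 100
  test_mut$inf02[1] <- NA
  set.seed(99)
  pp1 <- mciwindows:::preprocess_fold(train, test, schema, config)
  set.seed(99)
  pp2 <- mciwindows:::preprocess_fold(train, test_mut, schema, config)
  expect_identical(pp1$train, pp2$train)
  expect_identical(names(pp1$test), names(pp2$test))

  # the imputer fitted on train fills held-out cells with train values only
  m1 <- impute_fit(feat(train))
  filled_a <- impute_apply(m1, feat(test))
  filled_b <- impute_apply(m1, feat(test_mut))
  expect_equal(filled_a$inf01, filled_b$inf01 - 100)
  expect_equal(filled_b$inf02[1], m1$fills$inf02)

  # canonical fill: train {1,3}, test {NA, 100} -> {2, 100}
  m <- impute_fit(data.frame(x = c(1, 3)))
  expect_equal(impute_apply(m, data.frame(x = c(NA, 100)))$x, c(2, 100))
})

test_that("cfs merit matches its closed form", {
  # s = 1 reduces to the single feature-class correlation
  set.seed(5)
  y <- factor(rep(c("sMCI", "cMCI"), 50), levels = c("sMCI", "cMCI"))
  x <- data.frame(f1 = as.integer(y) + rnorm(100, sd = 0.3))
  m1 <- cfs_merit("f1", x, y)
  cors <- mciwindows:::cfs_correlations(x, y, "mdl_su")
  expect_equal(m1, unname(cors$cf["f1"]))

  # s = 2, r_cf = 0.5, r_ff = 1 -> 0.5 (plugging into the formula)
  cors2 <- list(cf = c(0.5, 0.5), ff = matrix(c(1, 1, 1, 1), 2))
  expect_equal(mciwindows:::merit_from_correlations(cors2, 1:2), 0.5)

  # no class association -> merit 0
  noise <- data.frame(n1 = rnorm(100), n2 = rnorm(100))
  expect_lt(cfs_merit(c("n1", "n2"), noise, y), 0.05)

  # constant feature has correlation 0 by convention
  cst <- data.frame(c1 = rep(1, 100))
  expect_equal(cfs_merit("c1", cst, y), 0)
})

test_that("cfs_select recovers planted signal and drops an exact duplicate", {
  hits <- 0L; dup_ok <- 0L; noise_excl <- 0L; n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    df <- planted_signal_examples(n = 300, n_informative = 3, n_noise = 20,
                                  seed = 100 + seed)
    feats <- df[setdiff(names(df), c("label", "class_defining_time",
                                     "patient_id"))]
    sel <- cfs_select(feats, df$label)
    if (all(c("inf01", "inf02", "inf03") %in% sel$features)) hits <- hits + 1L
    noise_excl <- noise_excl +
      (sum(grepl("^noise", sel$features)) <= 2)  # >= 90% of 20 excluded

    # duplicate an informative feature: at most one copy survives
    feats2 <- feats
    feats2$inf01_copy <- feats2$inf01
    sel2 <- cfs_select(feats2, df$label)
    if (sum(c("inf01", "inf01_copy") %in% sel2$features) <= 1)
      dup_ok <- dup_ok + 1L
  }
  expect_gte(hits, 18L)        # >= 90% of seeds
  expect_gte(noise_excl, 18L)
  expect_gte(dup_ok, 18L)
})

test_that("cfs_select is deterministic and order-invariant in merit", {
  df <- planted_signal_examples(n = 120, seed = 42)
  feats <- df[setdiff(names(df), c("label", "class_defining_time", "patient_id"))]
  s1 <- cfs_select(feats, df$label)
  s2 <- cfs_select(feats, df$label)
  expect_identical(s1, s2)
  # merit is invariant under feature permutation
  expect_equal(cfs_merit(c("inf01", "inf02"), feats, df$label),
               cfs_merit(c("inf02", "inf01"), feats, df$label))
  # single-feature schema returns that feature
  one <- cfs_select(feats["inf01"], df$label)
  expect_equal(one$features, "inf01")
})

test_that("the SMOTE inversion bound matches the proportion-swap formula", {
  expect_equal(max_smote_percent(10, 10), 0)
  expect_equal(max_smote_percent(94, 280), 100 * ((280 / 94)^2 - 1))
  expect_equal(max_smote_percent(94, 280), 787.28, tolerance = 1e-4)
  expect_equal(max_smote_percent(106, 190), 100 * ((190 / 106)^2 - 1))
  expect_equal(max_smote_percent(106, 190), 221.29, tolerance = 1e-4)
  expect_error(max_smote_percent(0, 5), "positive")

  # the inversion really swaps proportions: m grows to M^2/m
  m <- 94; M <- 280; n_inv <- max_smote_percent(m, M)
  new_m <- m * (1 + n_inv / 100)
  expect_equal(new_m / (new_m + M), M / (m + M))

  g <- smote_grid(94, 280)
  expect_true(0 %in% g)
  expect_true(any(abs(g - 100 * (280 / 94 - 1)) < 1e-9))  # balance point
  expect_true(max(g) <= n_inv + 1e-9)
  expect_identical(smote_grid(5, 5), 0)
})

test_that("smote adds floor(m*N/100) convex-combination minority rows", {
  df <- separable_examples(n = 30, seed = 8)   # 15 cMCI / 15 sMCI
  df <- df[c(1:10, 16:30), ]                    # 10 cMCI minority, 15 sMCI
  expect_identical(smote(df, 0), df)

  aug <- smote(df, percent = 100, seed = 4)
  expect_equal(sum(aug$label == "cMCI"), 20)
  expect_equal(sum(aug$label == "sMCI"), 15)
  # majority rows conserved exactly
  maj <- aug[aug$label == "sMCI" & !grepl("^synthetic", aug$patient_id), ]
  rownames(maj) <- NULL
  ref <- df[df$label == "sMCI", ]
  rownames(ref) <- NULL
  expect_identical(maj, ref)

  # convexity: every synthetic numeric value within the minority bounding box
  syn <- aug[grepl("^synthetic", aug$patient_id), c("f1", "f2", "f3")]
  mino <- df[df$label == "cMCI", c("f1", "f2", "f3")]
  for (cl in names(syn)) {
    expect_true(all(syn[[cl]] >= min(mino[[cl]]) - 1e-12))
    expect_true(all(syn[[cl]] <= max(mino[[cl]]) + 1e-12))
  }

  # reproducible under seed; count arithmetic with fractional percent
  expect_identical(smote(df, 73, seed = 2), smote(df, 73, seed = 2))
  expect_equal(sum(smote(df, 73, seed = 2)$label == "cMCI"),
               10 + floor(10 * 73 / 100))
  expect_error(smote(df[c(1, 11:25), ], 50), "at least 2")
})
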