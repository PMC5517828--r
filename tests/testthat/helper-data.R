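# Labeled feature tables with planted signal, for preprocessing and CV tests.

# Two well-separated Gaussian blobs: any sane classifier reaches AUC 1.
separable_examples <- function(n = 60, p = 3, gap = 8, seed = 1) {
  set.seed(seed)
  n1 <- n %/% 2; n0 <- n - n1
  x <- rbind(matrix(rnorm(n1 * p, mean = gap), n1, p),
             matrix(rnorm(n0 * p, mean = 0), n0, p))
  colnames(x) <- paste0("f", seq_len(p))
  df <- as.data.frame(x)
  df$label <- factor(rep(c("cMCI", "sMCI"), c(n1, n0)), levels = LABEL_LEVELS())
  df$class_defining_time <- 1
  df$patient_id <- sprintf("S%03d", seq_len(n))
  df
}

# Informative features shift with the class; noise features do not.
planted_signal_examples <- function(n = 200, n_informative = 3, n_noise = 20,
                                    shift = 1.5, seed = 1) {
  set.seed(seed)
  y <- rep(c("cMCI", "sMCI"), length.out = n)
  inf <- matrix(rnorm(n * n_informative), n) +
    shift * (y == "cMCI") %o% rep(1, n_informative)
  noise <- matrix(rnorm(n * n_noise), n)
  x <- cbind(inf, noise)
  colnames(x) <- c(sprintf("inf%02d", seq_len(n_informative)),
                   sprintf("noise%02d", seq_len(n_noise)))
  df <- as.data.frame(x)
  df$label <- factor(y, levels = LABEL_LEVELS())
  df$class_defining_time <- 1
  df$patient_id <- sprintf("S%03d", seq_len(n))
  df
}

LABEL_LEVELS <- function() c("sMCI", "cMCI")

as_example_set <- function(df, design = "window", k = 5) {
  structure(list(design = design, k = if (design == "window") k,
                 boundary = if (design == "window") "strict_paper",
                 schema = infer_schema(df[setdiff(names(df),
                   c("label", "class_defining_time", "patient_id"))]),
                 examples = df,
                 discarded = data.frame(patient_id = character(),
                                        reason = character())),
            class = "mci_example_set")
}

fast_nb_config <- function(fs = FALSE, mvi = TRUE, smote_percent = 0) {
  list(classifier = tw_classifier("nb", mode = "gaussian"),
       fs = fs, mvi = mvi, smote_percent = smote_percent)
}
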