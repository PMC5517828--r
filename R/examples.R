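DISCARD_REASONS <- c("no_followup", "censored_before_window",
                     "conversion_outside_window")

#' Summarize a diagnosis history
#'
#' Precomputes the quantities the labeling rules need: the time of the first
#' dementia evaluation (\code{t_conv}, \code{NA} if the patient never
#' converted during follow-up), the time of the last MCI evaluation
#' (\code{t_last_mci}) and whether any follow-up exists.
#'
#' @param evaluations data frame with columns \code{time_years},
#'   \code{diagnosis}, time-ordered (as returned by
#'   \code{\link{patient_history}}).
#' @return List with \code{t_conv}, \code{t_last_mci}, \code{has_followup}.
#' @export
summarize_history <- function(evaluations) {
  tm <- evaluations$time_years
  dem <- tm[evaluations$diagnosis == "DEMENTIA"]
  mci <- tm[evaluations$diagnosis == "MCI"]
  list(t_conv = if (length(dem)) min(dem) else NA_real_,
       t_last_mci = if (length(mci)) max(mci) else NA_real_,
       has_followup = nrow(evaluations) >= 2)
}

label_outcome <- function(kind, reason = NA_character_,
                          class_defining_time = NA_real_) {
  list(kind = kind, reason = reason, class_defining_time = class_defining_time)
}

#' Label a history under the First-Last design
#'
#' The conventional design: the class is the diagnosis at the patient's last
#' evaluation, regardless of the time elapsed since baseline. Patients without
#' follow-up are discarded.
#'
#' @inheritParams summarize_history
#' @return List with \code{kind} ("cMCI", "sMCI" or "discard"), a discard
#'   \code{reason}, and \code{class_defining_time} (the last evaluation time).
#' @export
label_first_last <- function(evaluations) {
  if (nrow(evaluations) < 2)
    return(label_outcome("discard", "no_followup"))
  last <- nrow(evaluations)
  kind <- if (evaluations$diagnosis[last] == "DEMENTIA") "cMCI" else "sMCI"
  label_outcome(kind, class_defining_time = evaluations$time_years[last])
}

#' Label a history under a time window of k years
#'
#' A patient is cMCI when dementia is first observed at a follow-up evaluation
#' strictly inside the window (time < k), sMCI when an MCI diagnosis is
#' observed at or beyond k years (the patient demonstrably had not converted
#' within the window). Otherwise the follow-up cannot decide the label and the
#' patient is discarded: still MCI but last seen before k years
#' (\code{censored_before_window}), or first seen demented only at/after k
#' years (\code{conversion_outside_window}) -- conversion may have occurred
#' either side of the boundary.
#'
#' @inheritParams summarize_history
#' @param k window width in years (> 0).
#' @param boundary how to treat a dementia diagnosis at exactly k years:
#'   \code{"strict_paper"} (default) requires conversion strictly inside the
#'   window, so t = k discards; \code{"inclusive"} counts it as cMCI.
#' @return As \code{\link{label_first_last}}; for cMCI
#'   \code{class_defining_time} is the first dementia evaluation, for sMCI the
#'   earliest MCI evaluation at or beyond k (the evaluation proving stability).
#' @export
label_window <- function(evaluations, k, boundary = c("strict_paper", "inclusive")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k <= 0)
    stop("window width k must be a positive number of years")
  s <- summarize_history(evaluations)
  if (!s$has_followup)
    return(label_outcome("discard", "no_followup"))
  converted_inside <- !is.na(s$t_conv) &&
    (if (boundary == "strict_paper") s$t_conv < k else s$t_conv <= k)
  if (converted_inside)
    return(label_outcome("cMCI", class_defining_time = s$t_conv))
  if (!is.na(s$t_last_mci) && s$t_last_mci >= k) {
    tm <- evaluations$time_years
    proof <- min(tm[evaluations$diagnosis == "MCI" & tm >= k])
    return(label_outcome("sMCI", class_defining_time = proof))
  }
  if (is.na(s$t_conv))
    label_outcome("discard", "censored_before_window")
  else
    label_outcome("discard", "conversion_outside_window")
}

#' Build a labeled example set from a cohort
#'
#' Applies \code{\link{label_first_last}} or \code{\link{label_window}} to
#' every patient. Each labeled example carries the patient's baseline features
#' only (follow-up measurements never enter the feature vector); every patient
#' lands either in \code{examples} or in the discard log, never both.
#'
#' @param cohort an \code{mci_cohort}.
#' @param design \code{"first_last"} or \code{"window"}.
#' @param k window width in years (required for \code{design = "window"}).
#' @param boundary see \code{\link{label_window}}.
#' @return An object of class \code{mci_example_set}: list with \code{design},
#'   \code{k}, \code{examples} (data frame: feature columns, then
#'   \code{label}, \code{class_defining_time}, \code{patient_id}) and
#'   \code{discarded} (data frame: \code{patient_id}, \code{reason}).
#' @export
build_example_set <- function(cohort, design = c("first_last", "window"),
                              k = NULL,
                              boundary = c("strict_paper", "inclusive")) {
  stopifnot(inherits(cohort, "mci_cohort"))
  design <- match.arg(design)
  boundary <- match.arg(boundary)
  if (design == "window" && is.null(k))
    stop("design = \"window\" requires a window width k")
  histories <- split_histories(cohort)
  if (!length(histories)) stop("empty cohort")
  ids <- names(histories)

  outcomes <- lapply(histories, function(h) {
    if (design == "first_last") label_first_last(h)
    else label_window(h, k, boundary)
  })
  kinds <- vapply(outcomes, `[[`, character(1), "kind")
  kept <- kinds != "discard"

  examples <- data.frame(
    label = factor(kinds[kept], levels = LABEL_LEVELS),
    class_defining_time = vapply(outcomes[kept], `[[`, numeric(1),
                                 "class_defining_time"),
    patient_id = ids[kept],
    stringsAsFactors = FALSE)
  if (!is.null(cohort$features)) {
    fmatch <- cohort$features[match(examples$patient_id,
                                    cohort$features$patient_id), , drop = FALSE]
    feat_cols <- setdiff(names(fmatch), "patient_id")
    examples <- cbind(fmatch[feat_cols], examples)
    rownames(examples) <- NULL
  }
  discarded <- data.frame(
    patient_id = ids[!kept],
    reason = vapply(outcomes[!kept], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  rownames(discarded) <- NULL

  structure(list(design = design,
                 k = if (design == "window") k else NULL,
                 boundary = if (design == "window") boundary else NULL,
                 schema = cohort$schema,
                 examples = examples, discarded = discarded),
            class = "mci_example_set")
}

#' @export
print.mci_example_set <- function(x, ...) {
  lbl <- if (x$design == "window") paste0("window k=", x$k, "y") else "first-last"
  cnt <- table(x$examples$label)
  cat("<mci_example_set> design: ", lbl, "\n  ",
      nrow(x$examples), " examples (", cnt[["sMCI"]], " sMCI, ",
      cnt[["cMCI"]], " cMCI), ", nrow(x$discarded), " discarded\n", sep = "")
  if (nrow(x$discarded))
    print(table(factor(x$discarded$reason, levels = DISCARD_REASONS)))
  invisible(x)
}

example_features <- function(es) {
  setdiff(names(es$examples), META_COLS)
}

#' Audit label monotonicity across windows
#'
#' A converter inside a small window must stay a converter in every larger
#' window, and a patient stable at a large window must be stable at every
#' smaller one. This audit re-labels every patient at each window and reports
#' violations of that pattern (an empty report is the expected outcome; a
#' non-empty one indicates corrupted histories or a labeling defect).
#'
#' @param cohort an \code{mci_cohort}.
#' @param windows increasing vector of at least two window widths (years).
#' @param boundary see \code{\link{label_window}}.
#' @return Data frame of violations (\code{patient_id}, \code{window_small},
#'   \code{window_large}, \code{label_small}, \code{label_large}); zero rows
#'   when the cohort is consistent. The full per-patient label matrix is
#'   attached as attribute \code{"labels"}.
#' @export
audit_monotonicity <- function(cohort, windows = c(2, 3, 4, 5),
                               boundary = c("strict_paper", "inclusive")) {
  boundary <- match.arg(boundary)
  if (length(windows) < 2 || is.unsorted(windows, strictly = TRUE))
    stop("windows must be at least two strictly increasing values")
  histories <- split_histories(cohort)
  labels <- t(vapply(histories, function(h)
    vapply(windows, function(k) label_window(h, k, boundary)$kind, character(1)),
    character(length(windows))))
  colnames(labels) <- paste0("k", windows)

  viol <- list()
  for (i in seq_along(windows)[-length(windows)]) {
    for (j in seq((i + 1), length(windows))) {
      bad_c <- labels[, i] == "cMCI" & labels[, j] != "cMCI"
      bad_s <- labels[, j] == "sMCI" & labels[, i] != "sMCI"
      bad <- bad_c | bad_s
      if (any(bad))
        viol[[length(viol) + 1]] <- data.frame(
          patient_id = rownames(labels)[bad],
          window_small = windows[i], window_large = windows[j],
          label_small = labels[bad, i], label_large = labels[bad, j],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(patient_id = character(), window_small = numeric(),
               window_large = numeric(), label_small = character(),
               label_large = character(), stringsAsFactors = FALSE)
  attr(out, "labels") <- labels
  out
}

#' Write an example set to CSV (with a discard-log sidecar)
#'
#' Column order is feature columns, then \code{label},
#' \code{class_defining_time}, \code{patient_id}. The discard log
#' (\code{patient_id}, \code{reason}) goes to \code{discard_path}.
#'
#' @param es an \code{mci_example_set}.
#' @param path output CSV path.
#' @param discard_path sidecar CSV path (default \code{<path>.discards.csv}).
#' @return \code{path}, invisibly.
#' @export
write_example_set <- function(es, path,
                              discard_path = paste0(path, ".discards.csv")) {
  stopifnot(inherits(es, "mci_example_set"))
  df <- es$examples[c(example_features(es), META_COLS)]
  write.csv(df, path, row.names = FALSE, na = "")
  write.csv(es$discarded, discard_path, row.names = FALSE)
  invisible(path)
}

#' Read an example set written by [write_example_set()]
#'
#' @param path CSV path.
#' @param schema \code{\link{feature_schema}} for the feature columns;
#'   inferred (numeric where every cell parses) when omitted.
#' @param design,k,boundary provenance fields to restore (not stored in the
#'   CSV itself).
#' @param discard_path sidecar CSV path; skipped if the file does not exist.
#' @return An \code{mci_example_set}.
#' @export
read_example_set <- function(path, schema = NULL, design = "window", k = NULL,
                             boundary = "strict_paper",
                             discard_path = paste0(path, ".discards.csv")) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  if (!all(META_COLS %in% names(df)))
    stop("example-set CSV is missing column(s): ",
         paste(setdiff(META_COLS, names(df)), collapse = ", "))
  feat_cols <- setdiff(names(df), META_COLS)
  if (is.null(schema)) {
    numish <- vapply(feat_cols, function(nm) {
      x <- trimws(df[[nm]]); x <- x[x != "" & toupper(x) != "NA"]
      length(x) == 0 || !anyNA(suppressWarnings(as.numeric(x)))
    }, logical(1))
    tokens <- lapply(feat_cols[!numish], function(nm) {
      x <- trimws(df[[nm]]); sort(unique(x[x != "" & toupper(x) != "NA"]))
    })
    names(tokens) <- feat_cols[!numish]
    schema <- feature_schema(numeric = feat_cols[numish], nominal = tokens)
  }
  for (nm in feat_cols) {
    x <- trimws(df[[nm]])
    x[x == "" | toupper(x) == "NA"] <- NA
    df[[nm]] <- if (is_numeric_feature(schema, nm)) as.numeric(x)
                else factor(x, levels = schema$nominal[[nm]])
  }
  bad <- setdiff(unique(df$label), LABEL_LEVELS)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  df$label <- factor(df$label, levels = LABEL_LEVELS)
  df$class_defining_time <- as.numeric(df$class_defining_time)
  discarded <- if (file.exists(discard_path))
    read.csv(discard_path, stringsAsFactors = FALSE,
             colClasses = c("character", "character"))
  else data.frame(patient_id = character(), reason = character(),
                  stringsAsFactors = FALSE)
  structure(list(design = design, k = k,
                 boundary = if (design == "window") boundary else NULL,
                 schema = schema,
                 examples = df[c(feat_cols, META_COLS)], discarded = discarded),
            class = "mci_example_set")
}
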