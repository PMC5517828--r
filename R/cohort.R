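DIAGNOSIS_LEVELS <- c("MCI", "DEMENTIA")
LABEL_LEVELS <- c("sMCI", "cMCI")
META_COLS <- c("label", "class_defining_time", "patient_id")

#' Longitudinal MCI cohort
#'
#' Container pairing a validated visits table (one row per clinical
#' evaluation) with an optional baseline feature table. Time is fractional
#' years since baseline; the baseline visit of every patient is an MCI
#' diagnosis at time 0, and dementia is absorbing (no MCI diagnosis after the
#' first dementia diagnosis).
#'
#' @param visits data frame with columns \code{patient_id},
#'   \code{time_years}, \code{diagnosis} ("MCI"/"DEMENTIA", case-insensitive).
#' @param features optional data frame with a \code{patient_id} column and one
#'   row per patient; missing values allowed.
#' @param schema optional \code{\link{feature_schema}}; inferred from
#'   \code{features} when omitted.
#' @param coerce_absorbing if \code{TRUE}, a history with an MCI diagnosis
#'   after a dementia diagnosis is truncated at the first dementia visit (with
#'   a warning) instead of raising an error.
#' @return An object of class \code{mci_cohort}.
#' @export
mci_cohort <- function(visits, features = NULL, schema = NULL,
                       coerce_absorbing = FALSE) {
  visits <- validate_visits(visits, coerce_absorbing = coerce_absorbing)
  if (!is.null(features)) {
    if (is.null(schema)) schema <- infer_schema(features)
    features <- validate_features(features, schema, visits)
  }
  structure(list(visits = visits, features = features, schema = schema),
            class = "mci_cohort")
}

validate_visits <- function(visits, coerce_absorbing = FALSE) {
  req <- c("patient_id", "time_years", "diagnosis")
  missing_cols <- setdiff(req, names(visits))
  if (length(missing_cols))
    stop("visits table is missing column(s): ", paste(missing_cols, collapse = ", "))
  visits <- visits[req]
  visits$patient_id <- as.character(visits$patient_id)
  if (!is.numeric(visits$time_years)) {
    suppressWarnings(tm <- as.numeric(as.character(visits$time_years)))
    if (anyNA(tm)) stop("non-numeric time_years value(s)")
    visits$time_years <- tm
  }
  if (anyNA(visits$time_years) || any(visits$time_years < 0))
    stop("time_years must be non-negative and non-missing")
  diag <- toupper(trimws(as.character(visits$diagnosis)))
  bad <- setdiff(unique(diag), DIAGNOSIS_LEVELS)
  if (length(bad))
    stop("unknown diagnosis token(s): ", paste(bad, collapse = ", "))
  visits$diagnosis <- factor(diag, levels = DIAGNOSIS_LEVELS)
  if (anyDuplicated(visits[c("patient_id", "time_years")]))
    stop("duplicate (patient_id, time_years) evaluation(s)")
  visits <- visits[order(visits$patient_id, visits$time_years), , drop = FALSE]
  rownames(visits) <- NULL

  keep <- rep(TRUE, nrow(visits))
  for (rows in split(seq_len(nrow(visits)), visits$patient_id)) {
    tm <- visits$time_years[rows]
    dg <- visits$diagnosis[rows]
    if (tm[1] != 0 || dg[1] != "MCI")
      stop("patient ", visits$patient_id[rows[1]],
           ": baseline must be an MCI evaluation at time 0")
    dem <- which(dg == "DEMENTIA")
    if (length(dem) && any(dg[seq(dem[1], length(dg))] == "MCI")) {
      if (coerce_absorbing) {
        warning("patient ", visits$patient_id[rows[1]],
                ": MCI evaluation after dementia; history truncated at first dementia visit")
        keep[rows[seq_along(rows) > dem[1]]] <- FALSE
      } else {
        stop("patient ", visits$patient_id[rows[1]],
             ": non-absorbing dementia (MCI evaluation after a dementia evaluation)")
      }
    }
  }
  visits <- visits[keep, , drop = FALSE]
  rownames(visits) <- NULL
  visits
}

validate_features <- function(features, schema, visits) {
  if (!"patient_id" %in% names(features))
    stop("features table is missing the patient_id column")
  features$patient_id <- as.character(features$patient_id)
  if (anyDuplicated(features$patient_id))
    stop("duplicate patient_id in features table")
  known <- unique(visits$patient_id)
  orphan <- setdiff(features$patient_id, known)
  if (length(orphan)) {
    warning("dropping ", length(orphan),
            " feature row(s) with no visits: ", paste(orphan, collapse = ", "))
    features <- features[features$patient_id %in% known, , drop = FALSE]
  }
  extra <- setdiff(names(features), c("patient_id", schema_features(schema)))
  if (length(extra))
    stop("feature column(s) not in schema: ", paste(extra, collapse = ", "))
  for (nm in schema$numeric) {
    if (!nm %in% names(features)) next
    x <- features[[nm]]
    if (!is.numeric(x)) {
      xc <- trimws(as.character(x))
      xc[xc == "" | toupper(xc) == "NA"] <- NA
      suppressWarnings(xn <- as.numeric(xc))
      if (any(!is.na(xc) & is.na(xn)))
        stop("non-numeric value(s) in numeric feature '", nm, "'")
      x <- xn
    }
    features[[nm]] <- x
  }
  for (nm in names(schema$nominal)) {
    if (!nm %in% names(features)) next
    x <- trimws(as.character(features[[nm]]))
    x[x == "" | toupper(x) == "NA" | is.na(x)] <- NA
    bad <- setdiff(unique(x[!is.na(x)]), schema$nominal[[nm]])
    if (length(bad))
      stop("token(s) outside schema for nominal feature '", nm, "': ",
           paste(bad, collapse = ", "))
    features[[nm]] <- factor(x, levels = schema$nominal[[nm]])
  }
  rownames(features) <- NULL
  features
}

#' Read a visits table
#'
#' CSV with header \code{patient_id,time_years,diagnosis}; diagnosis tokens
#' are case-insensitive \code{MCI}/\code{DEMENTIA}. Histories are grouped by
#' patient and sorted by time; baseline (MCI at time 0) and the absorbing
#' dementia rule are checked at load time.
#'
#' @param path CSV file path.
#' @inheritParams mci_cohort
#' @return An \code{mci_cohort} (without features).
#' @export
read_visits <- function(path, coerce_absorbing = FALSE) {
  visits <- read.csv(path, stringsAsFactors = FALSE)
  mci_cohort(visits, coerce_absorbing = coerce_absorbing)
}

#' Read a baseline feature table into a cohort
#'
#' One row per patient; empty cells and \code{NA} (case-insensitive) are
#' missing. Values are typed against the schema; imputation does not happen
#' here (it is fitted in-fold during cross-validation). Feature rows whose
#' patient id has no visit history are dropped with a warning.
#'
#' @param cohort an \code{mci_cohort} from \code{\link{read_visits}}.
#' @param path CSV file path.
#' @param schema optional \code{\link{feature_schema}}; inferred when omitted.
#' @return The cohort with \code{features} and \code{schema} filled in.
#' @export
read_features <- function(cohort, path, schema = NULL) {
  stopifnot(inherits(cohort, "mci_cohort"))
  feats <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  if (is.null(schema)) {
    # untyped CSV: columns where every non-missing cell parses as a number
    # are numeric, the rest nominal
    cols <- setdiff(names(feats), "patient_id")
    numish <- vapply(cols, function(nm) {
      x <- trimws(feats[[nm]]); x <- x[x != "" & toupper(x) != "NA"]
      length(x) == 0 || !anyNA(suppressWarnings(as.numeric(x)))
    }, logical(1))
    tokens <- lapply(cols[!numish], function(nm) {
      x <- trimws(feats[[nm]]); sort(unique(x[x != "" & toupper(x) != "NA"]))
    })
    names(tokens) <- cols[!numish]
    schema <- feature_schema(numeric = cols[numish], nominal = tokens)
  }
  cohort$features <- validate_features(feats, schema, cohort$visits)
  cohort$schema <- schema
  cohort
}

#' @export
print.mci_cohort <- function(x, ...) {
  n <- length(unique(x$visits$patient_id))
  cat("<mci_cohort> ", n, " patients, ", nrow(x$visits), " evaluations",
      sep = "")
  if (!is.null(x$features))
    cat(", ", length(schema_features(x$schema)), " features", sep = "")
  cat("\n")
  fu <- followup_times(x)
  cat("  follow-up (years): mean ", round(mean(fu), 2), " sd ",
      round(sd(fu), 2), "; no follow-up: ", sum(fu == 0), " patient(s)\n",
      sep = "")
  invisible(x)
}

patient_ids <- function(cohort) unique(cohort$visits$patient_id)

#' Extract one patient's evaluations
#'
#' @param cohort an \code{mci_cohort}.
#' @param id patient id.
#' @return Data frame of that patient's evaluations, time-ordered.
#' @export
patient_history <- function(cohort, id) {
  h <- cohort$visits[cohort$visits$patient_id == id, , drop = FALSE]
  if (!nrow(h)) stop("unknown patient id: ", id)
  rownames(h) <- NULL
  h
}

followup_times <- function(cohort) {
  vapply(split(cohort$visits$time_years, cohort$visits$patient_id), max,
         numeric(1))
}

split_histories <- function(cohort) {
  split(cohort$visits[c("time_years", "diagnosis")], cohort$visits$patient_id)
}
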