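#' SMOTE percentage at which class proportions invert
#'
#' Oversampling the minority class by \code{N}\% multiplies its count by
#' \code{1 + N/100}. The proportions are exactly swapped (minority takes the
#' majority's former share) when \code{1 + N/100 = (M/m)^2}, i.e.
#' \code{N = 100 * ((M/m)^2 - 1)}. This is the upper endpoint of the SMOTE
#' search grid; a balanced fold gives 0.
#'
#' @param minority,majority class counts (0 < minority <= majority).
#' @return The inversion percentage.
#' @export
max_smote_percent <- function(minority, majority) {
  if (minority <= 0) stop("minority class count must be positive")
  if (minority > majority) stop("minority count exceeds majority count")
  100 * ((majority / minority)^2 - 1)
}

#' SMOTE percentage grid for the model search
#'
#' Five evenly spaced percentages from 0 up to
#' \code{min(N_inv, 2 * N_balance)} where \code{N_inv} is
#' \code{\link{max_smote_percent}} and \code{N_balance = 100*(M/m - 1)} is the
#' percentage giving exact balance; the grid point closest to balance is
#' snapped onto it so 0 and the balance point are always searched.
#'
#' @inheritParams max_smote_percent
#' @param n_points grid size.
#' @return Sorted numeric vector of percentages (a single 0 when already
#'   balanced).
#' @export
smote_grid <- function(minority, majority, n_points = 5) {
  n_inv <- max_smote_percent(minority, majority)
  if (n_inv == 0) return(0)
  bal <- 100 * (majority / minority - 1)
  ub <- min(n_inv, 2 * bal)
  pts <- seq(0, ub, length.out = n_points)
  pts[which.min(abs(pts[-1] - bal)) + 1] <- bal
  sort(unique(pts))
}

#' SMOTE oversampling of the minority class
#'
#' Adds \code{floor(m * percent / 100)} synthetic minority rows. Each
#' synthetic row interpolates a seed minority row towards one of its
#' \code{k} nearest minority neighbors (Euclidean distance on the numeric
#' features) at a uniform random fraction of the segment; nominal attributes
#' are copied from the seed row. Majority rows are untouched.
#'
#' @param data data frame with a \code{label} factor column (levels
#'   \code{sMCI}/\code{cMCI}) plus feature columns; numeric features must be
#'   complete (impute first).
#' @param percent oversampling percentage (0 returns the input unchanged).
#' @param k number of nearest neighbors (capped at m - 1).
#' @param seed optional integer seed for reproducibility.
#' @return \code{data} with the synthetic rows appended (their
#'   \code{patient_id}, when present, is \code{"synthetic_<i>"}).
#' @export
smote <- function(data, percent, k = 5, seed = NULL) {
  stopifnot("label" %in% names(data))
  if (percent < 0) stop("percent must be non-negative")
  if (percent == 0) return(data)
  if (!is.null(seed)) set.seed(seed)

  counts <- table(data$label)
  minority <- names(counts)[which.min(counts)]
  m <- min(counts)
  if (m < 2) stop("minority class must have at least 2 rows")
  n_syn <- floor(m * percent / 100)
  if (n_syn == 0) return(data)

  feat_cols <- setdiff(names(data), META_COLS)
  num_cols <- feat_cols[vapply(data[feat_cols], is.numeric, logical(1))]
  min_rows <- which(data$label == minority)
  xm <- as.matrix(data[min_rows, num_cols, drop = FALSE])
  if (anyNA(xm)) stop("numeric features must be complete before SMOTE")

  k_eff <- min(k, m - 1)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_eff)]))

  seeds <- rep_len(seq_len(m), n_syn)
  syn <- data[min_rows[seeds], , drop = FALSE]
  for (i in seq_len(n_syn)) {
    s <- seeds[i]
    nb <- nn[s, sample.int(k_eff, 1)]
    gap <- runif(1)
    syn[i, num_cols] <- xm[s, ] + gap * (xm[nb, ] - xm[s, ])
  }
  if ("patient_id" %in% names(syn))
    syn$patient_id <- paste0("synthetic_", seq_len(n_syn))
  if ("class_defining_time" %in% names(syn))
    syn$class_defining_time <- NA_real_
  out <- rbind(data, syn)
  rownames(out) <- NULL
  out
}
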