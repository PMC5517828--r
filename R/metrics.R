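#' Area under the ROC curve (Mann-Whitney form)
#'
#' Pair-counting AUC: the fraction of (positive, negative) pairs where the
#' positive example scores higher, crediting 0.5 to ties. Equivalent to the
#' normalized Mann-Whitney U statistic; computed via midranks.
#'
#' @param scores numeric scores (higher = more converter-like).
#' @param labels factor or character with levels \code{sMCI}/\code{cMCI}.
#' @param positive the positive class (default \code{"cMCI"}).
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(scores, labels, positive = "cMCI") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (anyNA(scores)) stop("scores must be non-missing")
  r <- rank(scores)  # midranks credit ties 0.5 per pair
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity
#'
#' Sensitivity is the proportion of actual converters (cMCI) correctly
#' classified; specificity the proportion of stable patients (sMCI) correctly
#' identified. When a class is absent from \code{truth} its member is
#' \code{NA}, not 0.
#'
#' @param predicted,truth factors/characters with levels
#'   \code{sMCI}/\code{cMCI}.
#' @param positive the positive class (default \code{"cMCI"}).
#' @return Named numeric vector \code{c(sensitivity=, specificity=)}.
#' @export
sensitivity_specificity <- function(predicted, truth, positive = "cMCI") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  pos <- truth == positive
  sens <- if (any(pos)) mean(predicted[pos] == positive) else NA_real_
  spec <- if (any(!pos)) mean(predicted[!pos] != positive) else NA_real_
  c(sensitivity = sens, specificity = spec)
}
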