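comparison_result <- function(test, statistic, p_value, n,
                              extra = list(), warning_msg = NULL) {
  out <- c(list(test = test, statistic = unname(statistic),
                p_value = unname(p_value), n = n,
                significant = isTRUE(unname(p_value) < 0.05)), extra)
  if (!is.null(warning_msg)) out$note <- warning_msg
  structure(out, class = "tw_comparison")
}

#' @export
print.tw_comparison <- function(x, ...) {
  cat("<tw_comparison> ", x$test, ": statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4),
      if (!is.null(x$adjusted_p)) paste0(" (adjusted ", signif(x$adjusted_p, 4), ")"),
      ", n = ", x$n,
      if (x$significant) " *" else "", "\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Wilcoxon signed-rank test on paired metric series
#'
#' Two-sided paired test; zero differences are dropped (Wilcoxon convention)
#' and ties are mid-ranked. The exact null distribution is used when fewer
#' than \code{exact_below} non-zero differences remain (and no ties prevent
#' it), the normal approximation with continuity correction otherwise.
#'
#' @param a,b paired metric values (same length, same pairing index, e.g. the
#'   per-repeat mean AUC of two configurations under shared folds).
#' @param exact_below threshold on non-zero differences below which the exact
#'   distribution is used.
#' @return A \code{tw_comparison} (statistic = V, the positive-rank sum of
#'   \code{a - b}).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_below = 6) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  nz <- sum(d != 0)
  if (nz == 0) {
    warning("all paired differences are zero; p = 1")
    return(comparison_result("wilcoxon_signed_rank", NA_real_, 1, length(a)))
  }
  res <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = nz < exact_below,
                correct = TRUE))
  comparison_result("wilcoxon_signed_rank", res$statistic, res$p.value,
                    length(a), extra = list(n_nonzero = nz))
}

#' Friedman test across configurations
#'
#' Rank-based test of whether several configurations (classifiers) differ
#' across paired blocks (CV repeats): within each block the configurations
#' are ranked and the chi-square statistic tests equality of mean ranks.
#'
#' @param metric_matrix numeric matrix, configurations in rows, blocks in
#'   columns (e.g. 7 classifiers x 10 repeat-mean AUCs).
#' @return A \code{tw_comparison}.
#' @export
friedman <- function(metric_matrix) {
  metric_matrix <- as.matrix(metric_matrix)
  if (nrow(metric_matrix) < 3) stop("need at least 3 configurations")
  if (ncol(metric_matrix) < 2) stop("need at least 2 blocks")
  res <- friedman.test(t(metric_matrix))
  stat <- unname(res$statistic); p <- res$p.value
  if (is.nan(stat)) {  # every block fully tied: no evidence of differences
    stat <- 0; p <- 1
  }
  comparison_result("friedman", stat, p, ncol(metric_matrix),
                    extra = list(df = unname(res$parameter)))
}

#' Bonferroni correction
#'
#' \code{adjusted = min(1, p * family_size)}; the family size may exceed the
#' number of p-values supplied (e.g. when only some of a family of pairwise
#' comparisons are passed in).
#'
#' @param p numeric vector of raw p-values.
#' @param family_size the size of the comparison family (default
#'   \code{length(p)}).
#' @return Adjusted p-values, same order as \code{p}.
#' @export
bonferroni <- function(p, family_size = length(p)) {
  if (family_size < length(p))
    stop("family_size must be at least the number of p-values")
  pmin(1, p * family_size)
}

#' McNemar test on paired correctness flags
#'
#' Compares two classifiers (or two designs) on the same patients through the
#' discordant counts b (A correct, B wrong) and c (A wrong, B correct). The
#' reported statistic is always the continuity-corrected chi-square
#' \code{(|b-c|-1)^2/(b+c)}; the p-value uses that asymptotic distribution
#' when \code{b + c >= exact_below}, and the exact binomial otherwise
#' (\code{method} can force either).
#'
#' @param correct_a,correct_b logical vectors: per-patient correctness of the
#'   two conditions, identically indexed.
#' @param method \code{"auto"} (default), \code{"exact"} or
#'   \code{"asymptotic"}.
#' @param exact_below discordant-count threshold for the automatic switch.
#' @return A \code{tw_comparison} with \code{b} and \code{c} attached.
#' @export
mcnemar <- function(correct_a, correct_b, method = c("auto", "exact", "asymptotic"),
                    exact_below = 25) {
  method <- match.arg(method)
  stopifnot(length(correct_a) == length(correct_b))
  ok <- !is.na(correct_a) & !is.na(correct_b)
  a <- as.logical(correct_a[ok]); bb <- as.logical(correct_b[ok])
  b <- sum(a & !bb)
  cc <- sum(!a & bb)
  nd <- b + cc
  if (nd == 0) {
    warning("no discordant pairs; p = 1")
    return(comparison_result("mcnemar", 0, 1, length(a),
                             extra = list(b = b, c = cc)))
  }
  chisq <- (abs(b - cc) - 1)^2 / nd
  use_exact <- switch(method, auto = nd < exact_below,
                      exact = TRUE, asymptotic = FALSE)
  p <- if (use_exact) binom.test(b, nd, 0.5)$p.value
       else pchisq(chisq, df = 1, lower.tail = FALSE)
  comparison_result("mcnemar", chisq, p, length(a),
                    extra = list(b = b, c = cc,
                                 method = if (use_exact) "exact" else "asymptotic"))
}

#' McNemar comparison of two designs' out-of-fold predictions
#'
#' The Time-Windows and First-Last example sets generally differ in
#' membership (windows discard censored patients), so the comparison is
#' restricted to patients present in both and uses each run's majority
#' out-of-fold correctness. Note each design's correctness is with respect to
#' its own label definition.
#'
#' @param cv_a,cv_b \code{tw_cv} objects (e.g. \code{tw_search$best_cv} of the
#'   window and First-Last runs).
#' @param ... passed to \code{\link{mcnemar}}.
#' @return A \code{tw_comparison}; \code{b} counts patients only A got right,
#'   \code{c} patients only B got right.
#' @export
compare_designs <- function(cv_a, cv_b, ...) {
  stopifnot(inherits(cv_a, "tw_cv"), inherits(cv_b, "tw_cv"))
  shared <- intersect(cv_a$oof$patient_id, cv_b$oof$patient_id)
  if (!length(shared)) stop("no shared patients between the two runs")
  ia <- match(shared, cv_a$oof$patient_id)
  ib <- match(shared, cv_b$oof$patient_id)
  mcnemar(cv_a$oof$correct[ia], cv_b$oof$correct[ib], ...)
}
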