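# Correlation-based feature selection (CFS): subset merit
#   merit(S) = s * mean(r_cf) / sqrt(s + s*(s-1) * mean(r_ff))
# with r_cf the feature-class and r_ff the feature-feature correlations,
# measured by symmetrical uncertainty on supervised-MDL-discretized features
# (default) or by absolute Pearson correlation on ranks (fast alternative).

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Fayyad-Irani recursive minimum-description-length discretization.
# Returns numeric cut points (possibly none: the feature stays one bin).
mdl_cutpoints <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- as.integer(factor(y[ok]))
  if (!length(x)) return(numeric())
  o <- order(x)
  x <- x[o]; y <- y[o]
  k_all <- max(y)

  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 4L) return(numeric())
    xs <- x[lo:hi]; ys <- y[lo:hi]
    tot <- tabulate(ys, k_all)
    h_s <- entropy_bits(tot)
    if (h_s == 0) return(numeric())
    # candidate cuts: between adjacent distinct values
    cand <- which(diff(xs) > 0)
    if (!length(cand)) return(numeric())
    cum <- vapply(seq_len(k_all), function(cl) cumsum(ys == cl), numeric(n))
    best <- NULL; best_e <- Inf
    for (i in cand) {
      c1 <- cum[i, ]; c2 <- tot - c1
      e <- (i / n) * entropy_bits(c1) + ((n - i) / n) * entropy_bits(c2)
      if (e < best_e - 1e-12) { best_e <- e; best <- i }
    }
    gain <- h_s - best_e
    c1 <- cum[best, ]; c2 <- tot - c1
    k1 <- sum(c1 > 0); k2 <- sum(c2 > 0); k <- sum(tot > 0)
    delta <- log2(3^k - 2) - (k * h_s - k1 * entropy_bits(c1) -
                                k2 * entropy_bits(c2))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric())
    cut <- (xs[best] + xs[best + 1]) / 2
    c(recurse(lo, lo + best - 1L), cut, recurse(lo + best, hi))
  }
  sort(recurse(1L, length(x)))
}

discretize_mdl <- function(x, y) {
  cuts <- mdl_cutpoints(x, y)
  if (!length(cuts)) return(factor(rep("all", length(x))))
  cut(x, breaks = c(-Inf, cuts, Inf))
}

# Symmetrical uncertainty between two discrete vectors; NA is its own
# category so rows are never dropped.
symmetrical_uncertainty <- function(x, y) {
  x <- addNA(factor(x), ifany = TRUE)
  y <- addNA(factor(y), ifany = TRUE)
  joint <- table(x, y)
  hx <- entropy_bits(rowSums(joint))
  hy <- entropy_bits(colSums(joint))
  if (hx + hy == 0) return(0)
  hxy <- entropy_bits(as.vector(joint))
  max(0, 2 * (hx + hy - hxy) / (hx + hy))
}

# Feature-class and feature-feature correlation tables for CFS.
cfs_correlations <- function(data, label,
                             measure = c("mdl_su", "rank_pearson")) {
  measure <- match.arg(measure)
  feats <- setdiff(names(data), META_COLS)
  p <- length(feats)
  if (measure == "mdl_su") {
    disc <- lapply(feats, function(nm) {
      x <- data[[nm]]
      if (is.numeric(x)) discretize_mdl(x, label) else factor(x)
    })
    names(disc) <- feats
    cf <- vapply(disc, symmetrical_uncertainty, numeric(1), y = label)
    ff <- diag(1, p)
    if (p > 1)
      for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
        ff[i, j] <- ff[j, i] <- symmetrical_uncertainty(disc[[i]], disc[[j]])
      }
  } else {
    num <- vapply(feats, function(nm) {
      x <- data[[nm]]
      rank(if (is.numeric(x)) x else as.integer(factor(x)),
           na.last = "keep")
    }, numeric(nrow(data)))
    ycode <- rank(as.integer(label))
    safe_cor <- function(a, b) {
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(0)
      abs(stats::cor(a[ok], b[ok]))
    }
    cf <- apply(num, 2, safe_cor, b = ycode)
    ff <- diag(1, p)
    if (p > 1)
      for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
        ff[i, j] <- ff[j, i] <- safe_cor(num[, i], num[, j])
      }
  }
  dimnames(ff) <- list(feats, feats)
  names(cf) <- feats
  list(cf = cf, ff = ff, features = feats)
}

merit_from_correlations <- function(cors, idx) {
  s <- length(idx)
  if (!s) return(0)
  rcf <- mean(cors$cf[idx])
  rff <- if (s > 1) {
    sub <- cors$ff[idx, idx, drop = FALSE]
    (sum(sub) - s) / (s * (s - 1))
  } else 0
  denom <- s + s * (s - 1) * rff
  if (denom <= 0) return(0)
  s * rcf / sqrt(denom)
}

#' CFS merit of a feature subset
#'
#' Scores a subset by high feature-class correlation and low feature-feature
#' redundancy: \code{merit = s * rcf / sqrt(s + s*(s-1)*rff)} for subset size
#' \code{s}, mean feature-class correlation \code{rcf} and mean pairwise
#' feature-feature correlation \code{rff}. A single feature reduces to its
#' class correlation; duplicated features are penalized through the
#' denominator. Constant features have correlation 0 by convention.
#'
#' @param subset character vector of feature names.
#' @param data data frame holding the features.
#' @param label binary class factor (levels \code{sMCI}, \code{cMCI}).
#' @param measure \code{"mdl_su"}: symmetrical uncertainty on features
#'   discretized by supervised MDL binning (default); \code{"rank_pearson"}:
#'   absolute Pearson correlation on ranks.
#' @return Merit, a non-negative scalar.
#' @export
cfs_merit <- function(subset, data, label,
                      measure = c("mdl_su", "rank_pearson")) {
  if (!length(subset)) stop("subset must be non-empty")
  if (nlevels(factor(label[!is.na(label)])) < 2)
    stop("both classes must be present")
  missing_f <- setdiff(subset, names(data))
  if (length(missing_f))
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  cors <- cfs_correlations(data[subset], label, measure)
  merit_from_correlations(cors, seq_along(subset))
}

#' Select a feature subset with CFS best-first search
#'
#' Forward best-first search over subsets maximizing \code{\link{cfs_merit}},
#' stopping after \code{max_stale} consecutive expansions without improvement
#' (the canonical search configuration). Ties are broken by feature column
#' order, making the search deterministic.
#'
#' @inheritParams cfs_merit
#' @param max_stale consecutive non-improving expansions before stopping.
#' @return Object of class \code{tw_feature_subset}: list with
#'   \code{features} (selected names, in column order) and \code{merit}.
#' @export
cfs_select <- function(data, label, measure = c("mdl_su", "rank_pearson"),
                       max_stale = 5) {
  measure <- match.arg(measure)
  cors <- cfs_correlations(data, label, measure)
  p <- length(cors$features)
  key <- function(idx) paste0("s", paste(idx, collapse = ","))

  open_sets <- list(integer())
  open_merit <- 0
  visited <- new.env(hash = TRUE)
  assign(key(integer()), TRUE, envir = visited)
  best_idx <- integer(); best_merit <- 0
  stale <- 0L

  while (length(open_sets) && stale < max_stale) {
    at <- which.max(open_merit)  # first max: deterministic tie-break
    node <- open_sets[[at]]
    open_sets <- open_sets[-at]; open_merit <- open_merit[-at]
    improved <- FALSE
    for (f in setdiff(seq_len(p), node)) {
      child <- sort(c(node, f))
      ck <- key(child)
      if (exists(ck, envir = visited, inherits = FALSE)) next
      assign(ck, TRUE, envir = visited)
      m <- merit_from_correlations(cors, child)
      open_sets[[length(open_sets) + 1]] <- child
      open_merit <- c(open_merit, m)
      if (m > best_merit + 1e-10) {
        best_merit <- m; best_idx <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(features = cors$features[best_idx], merit = best_merit,
                 measure = measure),
            class = "tw_feature_subset")
}

#' @export
print.tw_feature_subset <- function(x, ...) {
  cat("<tw_feature_subset> ", length(x$features), " feature(s), merit ",
      round(x$merit, 4), " (", x$measure, ")\n", sep = "")
  if (length(x$features)) cat("  ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
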