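#' Fit a mean/mode imputation model on training rows
#'
#' Numeric features are filled with the training mean, nominal features with
#' the training mode (ties broken by the lexicographically smallest token).
#' The model is a pure function of the training rows: apply it to held-out
#' rows with \code{\link{impute_apply}} and no information flows back.
#'
#' @param train data frame of training rows (feature columns; extra metadata
#'   columns such as \code{label} are ignored).
#' @param schema \code{\link{feature_schema}}; inferred when omitted.
#' @return Object of class \code{tw_impute}: named list of fill values.
#' @export
impute_fit <- function(train, schema = NULL) {
  if (is.null(schema)) schema <- infer_schema(train)
  feats <- intersect(schema_features(schema), names(train))
  fills <- lapply(feats, function(nm) {
    x <- train[[nm]]
    if (all(is.na(x)))
      stop("feature '", nm, "' is entirely missing in the training rows")
    if (is_numeric_feature(schema, nm)) {
      mean(x, na.rm = TRUE)
    } else {
      tab <- table(x)  # table() is over sorted levels: first max = smallest token
      names(tab)[which.max(tab)]
    }
  })
  names(fills) <- feats
  structure(list(fills = fills, schema = schema), class = "tw_impute")
}

#' Apply a fitted imputation model
#'
#' Only missing cells change; complete rows pass through untouched.
#'
#' @param model a \code{tw_impute} from \code{\link{impute_fit}}.
#' @param rows data frame to fill.
#' @return \code{rows} with missing feature cells replaced by the training
#'   fill values.
#' @export
impute_apply <- function(model, rows) {
  stopifnot(inherits(model, "tw_impute"))
  feats <- intersect(names(rows), schema_features(model$schema))
  unknown <- setdiff(feats, names(model$fills))
  if (length(unknown))
    stop("feature(s) not covered by the fitted imputation model: ",
         paste(unknown, collapse = ", "))
  for (nm in feats) {
    miss <- is.na(rows[[nm]])
    if (!any(miss)) next
    if (is_numeric_feature(model$schema, nm)) {
      rows[[nm]][miss] <- model$fills[[nm]]
    } else {
      rows[[nm]][miss] <- factor(model$fills[[nm]],
                                 levels = levels(rows[[nm]]))
    }
  }
  rows
}
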