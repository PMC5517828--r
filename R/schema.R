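#' Feature schema
#'
#' Declares the type of every baseline feature: numeric, or nominal with a
#' fixed token set. Feature tables are validated against the schema on read;
#' unknown nominal tokens are errors, so typos never silently become new
#' categories.
#'
#' @param numeric character vector of numeric feature names.
#' @param nominal named list; each element is the character vector of allowed
#'   tokens for that nominal feature.
#' @return An object of class \code{mci_schema}.
#' @examples
#' feature_schema(numeric = c("age", "mmse"),
#'                nominal = list(sex = c("f", "m")))
#' @export
feature_schema <- function(numeric = character(), nominal = list()) {
  numeric <- as.character(numeric)
  if (length(nominal) && (is.null(names(nominal)) || any(names(nominal) == "")))
    stop("every nominal feature must be named")
  nominal <- lapply(nominal, as.character)
  all_names <- c(numeric, names(nominal))
  if (anyDuplicated(all_names))
    stop("duplicate feature names in schema: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  structure(list(numeric = numeric, nominal = nominal),
            class = "mci_schema")
}

#' @export
print.mci_schema <- function(x, ...) {
  cat("<mci_schema> ", length(x$numeric), " numeric, ",
      length(x$nominal), " nominal feature(s)\n", sep = "")
  invisible(x)
}

schema_features <- function(schema) c(schema$numeric, names(schema$nominal))

is_numeric_feature <- function(schema, name) name %in% schema$numeric

#' Infer a schema from a typed feature data frame
#'
#' Numeric columns become numeric features; character and factor columns
#' become nominal features whose token set is the observed values.
#'
#' @param features data frame of baseline features (a \code{patient_id}
#'   column, if present, is ignored).
#' @return An \code{\link{feature_schema}} object.
#' @export
infer_schema <- function(features) {
  cols <- setdiff(names(features), "patient_id")
  num <- cols[vapply(features[cols], is.numeric, logical(1))]
  nom <- setdiff(cols, num)
  tokens <- lapply(features[nom], function(x) {
    lv <- if (is.factor(x)) levels(x) else sort(unique(as.character(x[!is.na(x)])))
    as.character(lv)
  })
  feature_schema(numeric = num, nominal = tokens)
}

#' Read a schema from a key/value config file
#'
#' One feature per line, \code{name: numeric} or
#' \code{name: nominal(tok1|tok2|...)}. Blank lines and \code{#} comments are
#' ignored.
#'
#' @param path file path.
#' @return An \code{\link{feature_schema}} object.
#' @export
read_schema <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  numeric <- character()
  nominal <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("malformed schema line: ", ln)
    name <- trimws(m[2]); kind <- trimws(m[3])
    if (kind == "numeric") {
      numeric <- c(numeric, name)
    } else if (grepl("^nominal\\(.*\\)$", kind)) {
      toks <- strsplit(sub("^nominal\\((.*)\\)$", "\\1", kind), "|", fixed = TRUE)[[1]]
      nominal[[name]] <- trimws(toks)
    } else stop("unknown feature kind '", kind, "' for feature '", name, "'")
  }
  feature_schema(numeric = numeric, nominal = nominal)
}

#' Write a schema to the key/value config format read by [read_schema()]
#'
#' @param schema an \code{mci_schema}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "mci_schema"))
  lines <- c(paste0(schema$numeric, ": numeric"),
             vapply(names(schema$nominal), function(n)
               paste0(n, ": nominal(", paste(schema$nominal[[n]], collapse = "|"), ")"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
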