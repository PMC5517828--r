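# Classifier adapter layer. Each family is delegated to an established
# implementation (e1071, rpart, randomForest, class, glmnet) behind a uniform
# fit / score-probability contract so the cross-validation protocol never
# touches classifier internals. The positive class is cMCI throughout.

CLASSIFIER_FAMILIES <- c("nb", "dt", "svm_rbf", "svm_poly", "knn", "rf", "lr")

#' Classifier configuration
#'
#' @param family one of \code{"nb"} (Naive Bayes: \code{mode} =
#'   \code{"gaussian"}, \code{"supervised_discretization"} or
#'   \code{"kernel_density"}), \code{"dt"} (decision tree, \code{cp}),
#'   \code{"svm_rbf"} (\code{cost}, \code{gamma}), \code{"svm_poly"}
#'   (\code{cost}, \code{degree}), \code{"knn"} (\code{k}), \code{"rf"}
#'   (\code{iterations}) or \code{"lr"} (ridge logistic regression,
#'   \code{ridge}).
#' @param ... named parameters for the family.
#' @return Object of class \code{tw_classifier}.
#' @export
tw_classifier <- function(family, ...) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  params <- list(...)
  defaults <- switch(family,
    nb = list(mode = "gaussian"),
    dt = list(cp = 0.05),
    svm_rbf = list(cost = 1, gamma = 0.1),
    svm_poly = list(cost = 1, degree = 2),
    knn = list(k = 5),
    rf = list(iterations = 30),
    lr = list(ridge = 1e-8))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults), class = "tw_classifier")
}

#' @export
print.tw_classifier <- function(x, ...) {
  cat("<tw_classifier> ", x$family, " (",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Families that cannot score rows with missing values: imputation is forced
# for them even when the MVI search switch is off.
needs_complete <- function(family) {
  family %in% c("svm_rbf", "svm_poly", "knn", "rf", "lr")
}

classifier_label <- function(clf) {
  paste0(clf$family, "(",
         paste(names(clf$params), unlist(clf$params), sep = "=",
               collapse = ","), ")")
}

# --- design-matrix helpers (knn, lr need numeric matrices) -----------------

encode_fit <- function(train, feat_cols) {
  num <- feat_cols[vapply(train[feat_cols], is.numeric, logical(1))]
  nom <- setdiff(feat_cols, num)
  mu <- vapply(train[num], mean, numeric(1))
  sdev <- vapply(train[num], sd, numeric(1))
  sdev[is.na(sdev) | sdev == 0] <- 1
  list(num = num, nom = nom, mu = mu, sd = sdev,
       levels = lapply(train[nom], levels))
}

encode_apply <- function(enc, data) {
  parts <- list()
  if (length(enc$num)) {
    x <- as.matrix(data[enc$num])
    parts$num <- sweep(sweep(x, 2, enc$mu), 2, enc$sd, "/")
  }
  for (nm in enc$nom) {
    lv <- enc$levels[[nm]]
    f <- factor(as.character(data[[nm]]), levels = lv)
    oh <- matrix(0, nrow(data), length(lv),
                 dimnames = list(NULL, paste0(nm, "_", lv)))
    oh[cbind(seq_len(nrow(data)), as.integer(f))] <- 1
    parts[[nm]] <- oh
  }
  do.call(cbind, parts)
}

# --- hand-rolled kernel-density Naive Bayes (no installed package offers a
#     KDE class-conditional option; gaussian and discretized modes delegate
#     to e1071) ---------------------------------------------------------------

kde_nb_fit <- function(train, feat_cols) {
  y <- train$label
  prior <- table(y) / length(y)
  models <- lapply(feat_cols, function(nm) {
    x <- train[[nm]]
    if (is.numeric(x)) {
      lapply(levels(y), function(cl) {
        v <- x[y == cl & !is.na(x)]
        if (length(v) < 2 || sd(v) == 0)
          list(type = "gauss", mu = mean(v), sd = max(sd(v), 1e-6, na.rm = TRUE))
        else list(type = "kde", v = v, bw = stats::bw.nrd0(v))
      })
    } else {
      lapply(levels(y), function(cl) {
        tab <- table(x[y == cl])
        list(type = "cat", prob = (tab + 1) / sum(tab + 1))  # Laplace
      })
    }
  })
  names(models) <- feat_cols
  list(prior = prior, models = models, classes = levels(y))
}

kde_nb_score <- function(fit, data, feat_cols) {
  n <- nrow(data)
  loglik <- matrix(rep(log(as.numeric(fit$prior)), each = n), n, 2)
  for (nm in feat_cols) {
    x <- data[[nm]]
    for (ci in 1:2) {
      m <- fit$models[[nm]][[ci]]
      ll <- if (m$type == "kde") {
        vapply(x, function(xi) {
          if (is.na(xi)) 0 else log(max(mean(dnorm(xi, m$v, m$bw)), 1e-300))
        }, numeric(1))
      } else if (m$type == "gauss") {
        ifelse(is.na(x), 0, dnorm(x, m$mu, m$sd, log = TRUE))
      } else {
        p <- m$prob[as.character(x)]
        ifelse(is.na(x) | is.na(p), 0, log(as.numeric(p)))
      }
      loglik[, ci] <- loglik[, ci] + ll
    }
  }
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post[, match("cMCI", fit$classes)] / rowSums(post)
}

# --- fit / score ------------------------------------------------------------

#' Fit a classifier on a labeled example table
#'
#' @param clf a \code{\link{tw_classifier}}.
#' @param train data frame with feature columns and a \code{label} factor.
#' @return Object of class \code{tw_fit} with a \code{\link{predict_prob}}
#'   method; scores are probabilities of the positive class (cMCI).
#' @export
fit_classifier <- function(clf, train) {
  stopifnot(inherits(clf, "tw_classifier"))
  feat_cols <- setdiff(names(train), META_COLS)
  if (!length(feat_cols)) stop("no feature columns")
  y <- droplevels(train$label)
  if (nlevels(y) < 2) stop("both classes must be present in the training rows")
  train <- train[c(feat_cols, "label")]
  train$label <- factor(train$label, levels = LABEL_LEVELS)
  p <- clf$params
  backend <- switch(clf$family,
    nb = {
      mode <- match.arg(p$mode, c("gaussian", "supervised_discretization",
                                  "kernel_density"))
      if (mode == "gaussian") {
        list(kind = "e1071_nb",
             fit = e1071::naiveBayes(label ~ ., data = train, laplace = 1))
      } else if (mode == "supervised_discretization") {
        num <- feat_cols[vapply(train[feat_cols], is.numeric, logical(1))]
        cuts <- lapply(train[num], mdl_cutpoints, y = train$label)
        tr2 <- train
        for (nm in num) tr2[[nm]] <- apply_cuts(tr2[[nm]], cuts[[nm]])
        list(kind = "e1071_nb_disc", cuts = cuts, num = num,
             fit = e1071::naiveBayes(label ~ ., data = tr2, laplace = 1))
      } else {
        list(kind = "kde_nb", fit = kde_nb_fit(train, feat_cols))
      }
    },
    dt = list(kind = "rpart",
              fit = rpart::rpart(label ~ ., data = train, method = "class",
                                 control = rpart::rpart.control(
                                   cp = p$cp, xval = 0))),
    svm_rbf = list(kind = "svm",
                   fit = e1071::svm(label ~ ., data = train, kernel = "radial",
                                    cost = p$cost, gamma = p$gamma,
                                    scale = FALSE)),
    svm_poly = list(kind = "svm",
                    fit = e1071::svm(label ~ ., data = train,
                                     kernel = "polynomial", cost = p$cost,
                                     degree = p$degree, coef0 = 1,
                                     scale = FALSE)),
    knn = {
      enc <- encode_fit(train, feat_cols)
      list(kind = "knn", enc = enc, x = encode_apply(enc, train),
           y = train$label, k = p$k)
    },
    rf = list(kind = "rf",
              fit = randomForest::randomForest(label ~ ., data = train,
                                               ntree = p$iterations)),
    lr = {
      enc <- encode_fit(train, feat_cols)
      x <- encode_apply(enc, train)
      if (ncol(x) >= 2) {
        list(kind = "glmnet", enc = enc,
             fit = glmnet::glmnet(x, train$label, family = "binomial",
                                  alpha = 0, lambda = p$ridge,
                                  standardize = FALSE))
      } else {
        df <- data.frame(x1 = x[, 1], label = train$label)
        list(kind = "glm", enc = enc,
             fit = suppressWarnings(stats::glm(label ~ x1, df,
                                               family = "binomial")))
      }
    })
  structure(list(clf = clf, feat_cols = feat_cols, backend = backend),
            class = "tw_fit")
}

apply_cuts <- function(x, cuts) {
  if (!length(cuts)) factor(rep("all", length(x)))
  else cut(x, breaks = c(-Inf, cuts, Inf))
}

#' Score the probability of conversion (cMCI)
#'
#' @param fit a \code{tw_fit} from \code{\link{fit_classifier}}.
#' @param newdata data frame with the training feature columns.
#' @return Numeric vector of P(cMCI) in [0, 1].
#' @export
predict_prob <- function(fit, newdata) {
  stopifnot(inherits(fit, "tw_fit"))
  missing_f <- setdiff(fit$feat_cols, names(newdata))
  if (length(missing_f))
    stop("newdata is missing feature(s): ", paste(missing_f, collapse = ", "))
  newdata <- newdata[fit$feat_cols]
  b <- fit$backend
  pr <- switch(b$kind,
    e1071_nb = predict(b$fit, newdata, type = "raw")[, "cMCI"],
    e1071_nb_disc = {
      for (nm in b$num) newdata[[nm]] <- apply_cuts(newdata[[nm]], b$cuts[[nm]])
      predict(b$fit, newdata, type = "raw")[, "cMCI"]
    },
    kde_nb = kde_nb_score(b$fit, newdata, fit$feat_cols),
    rpart = predict(b$fit, newdata, type = "prob")[, "cMCI"],
    svm = {
      dv <- attr(predict(b$fit, newdata, decision.values = TRUE),
                 "decision.values")
      # decision values are oriented "first/second" of the colname label
      pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
      score <- if (pair[1] == "cMCI") dv[, 1] else -dv[, 1]
      stats::plogis(score)
    },
    knn = {
      xte <- encode_apply(b$enc, newdata)
      pred <- class::knn(b$x, xte, b$y, k = min(b$k, nrow(b$x)), prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "cMCI", win, 1 - win)
    },
    rf = predict(b$fit, newdata, type = "prob")[, "cMCI"],
    glmnet = as.numeric(predict(b$fit, encode_apply(b$enc, newdata),
                                type = "response")),
    glm = {
      df <- data.frame(x1 = encode_apply(b$enc, newdata)[, 1])
      as.numeric(predict(b$fit, df, type = "response"))
    })
  unname(pmin(pmax(as.numeric(pr), 0), 1))
}
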