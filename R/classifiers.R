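# Pluggable two-class classifiers behind one fit/predict interface.
# `fit(X, y)` takes a numeric matrix and a 2-level factor; `predict` returns
# a factor with the same levels. Columns constant in the training data are
# dropped before fitting (several backends reject zero-variance inputs).

drop_constant_cols <- function(X) {
  keep <- apply(X, 2, function(v) diff(range(v)) > 0)
  if (!any(keep)) keep[1] <- TRUE
  keep
}

#' Construct a classifier backend
#'
#' Returns a fit/predict pair used by the cross-validation fitness and the
#' evaluation helpers. Available backends: `"xgboost"` (gradient-boosted
#' trees, the default), `"logistic"` (binomial GLM), `"lda"` (linear
#' discriminant analysis), `"tree"` (CART), `"nb"` (Gaussian naive Bayes).
#' All are deterministic given `seed`.
#'
#' @param id Backend name.
#' @param seed Integer seed passed to stochastic backends.
#' @param params Optional named list of backend hyperparameters (currently
#'   forwarded to xgboost: `nrounds`, `max_depth`, `eta`).
#' @return List of class `"iwoa_classifier"` with elements `id`, `fit`,
#'   `predict`.
#' @export
make_classifier <- function(id = c("xgboost", "logistic", "lda", "tree",
                                   "nb"),
                            seed = 1, params = list()) {
  id <- match.arg(id)
  cls <- switch(id,
    xgboost = {
      nrounds <- params$nrounds %||% 30
      max_depth <- params$max_depth %||% 3
      eta <- params$eta %||% 0.3
      list(
        fit = function(X, y) {
          keep <- drop_constant_cols(X)
          lv <- levels(y)
          dtrain <- xgboost::xgb.DMatrix(X[, keep, drop = FALSE],
                                         label = as.numeric(y == lv[2]))
          booster <- withr::with_seed(seed,
            xgboost::xgb.train(
              params = list(objective = "binary:logistic",
                            max_depth = max_depth, eta = eta, nthread = 1),
              data = dtrain, nrounds = nrounds, verbose = 0))
          list(booster = booster, keep = keep, levels = lv)
        },
        predict = function(model, X) {
          p <- stats::predict(model$booster,
                              xgboost::xgb.DMatrix(
                                X[, model$keep, drop = FALSE]))
          factor(model$levels[1 + (p > 0.5)], levels = model$levels)
        })
    },
    logistic = list(
      fit = function(X, y) {
        keep <- drop_constant_cols(X)
        lv <- levels(y)
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, X[, keep, drop = FALSE]),
                         as.numeric(y == lv[2]),
                         family = stats::binomial()))
        list(coef = fit$coefficients, keep = keep, levels = lv)
      },
      predict = function(model, X) {
        eta <- cbind(1, X[, model$keep, drop = FALSE]) %*%
          ifelse(is.na(model$coef), 0, model$coef)
        factor(model$levels[1 + (eta > 0)], levels = model$levels)
      }),
    lda = list(
      fit = function(X, y) {
        keep <- drop_constant_cols(X)
        # collinear predictors (e.g. iqr = q3 - q1) are expected; lda
        # handles them by dropping discriminant directions
        list(lda = suppressWarnings(
               MASS::lda(X[, keep, drop = FALSE], grouping = y)),
             keep = keep, levels = levels(y))
      },
      predict = function(model, X) {
        stats::predict(model$lda, X[, model$keep, drop = FALSE])$class
      }),
    tree = list(
      fit = function(X, y) {
        d <- as.data.frame(X)
        d$.y <- y
        list(tree = rpart::rpart(.y ~ ., data = d,
                                 method = "class",
                                 control = rpart::rpart.control(xval = 0)),
             levels = levels(y))
      },
      predict = function(model, X) {
        stats::predict(model$tree, as.data.frame(X), type = "class")
      }),
    nb = list(
      fit = function(X, y) {
        keep <- drop_constant_cols(X)
        list(nb = e1071::naiveBayes(X[, keep, drop = FALSE], y),
             keep = keep, levels = levels(y))
      },
      predict = function(model, X) {
        stats::predict(model$nb, X[, model$keep, drop = FALSE])
      })
  )
  structure(c(list(id = id, seed = seed), cls), class = "iwoa_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_label_factor <- function(label) {
  lv <- sort(unique(as.character(label)))
  # canonical behavior order: drinking (0) before eating (1) when present
  if (setequal(lv, c("eating", "drinking"))) lv <- c("drinking", "eating")
  factor(as.character(label), levels = lv)
}
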