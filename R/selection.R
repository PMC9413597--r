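#' Fitness configuration for wrapper feature selection
#'
#' @param alpha Weight of the classification-error term (default 0.99).
#' @param beta Weight of the subset-size term; must equal `1 - alpha`.
#' @param cv_folds Number of stratified CV folds (default 5).
#' @param classifier A classifier id for [make_classifier()] or an
#'   `iwoa_classifier` object (default `"xgboost"`).
#' @param cv_seed Seed controlling the CV fold assignment.
#' @param classifier_params Hyperparameters forwarded to
#'   [make_classifier()].
#' @return A list of class `"fitness_config"`.
#' @export
fitness_config <- function(alpha = 0.99, beta = 1 - alpha, cv_folds = 5,
                           classifier = "xgboost", cv_seed = 1,
                           classifier_params = list()) {
  if (abs(beta - (1 - alpha)) > 1e-12)
    stop("`beta` must equal 1 - alpha")
  if (cv_folds < 2) stop("`cv_folds` must be >= 2")
  if (!inherits(classifier, "iwoa_classifier"))
    classifier <- make_classifier(classifier, seed = cv_seed,
                                  params = classifier_params)
  structure(list(alpha = alpha, beta = beta, cv_folds = as.integer(cv_folds),
                 classifier = classifier, cv_seed = as.integer(cv_seed)),
            class = "fitness_config")
}

#' Decode a continuous position into a feature mask
#'
#' Bit `j` is set iff `position[j] > 0.5`. If no coordinate exceeds the
#' threshold, the bit of the largest coordinate is set (first index on
#' ties), so the mask always selects at least one feature.
#'
#' @param position Numeric vector in `[0, 1]^d`.
#' @return Logical vector of the same length.
#' @export
decode_mask <- function(position) {
  bits <- position > 0.5
  if (!any(bits)) bits[which.max(position)] <- TRUE
  bits
}

#' Subset-penalized selection fitness
#'
#' `alpha * (1 - acc) + beta * feasel / numfea`: the weighted sum of the
#' cross-validated error rate and the fraction of features retained.
#' Smaller is better; with `alpha = 0.99` accuracy dominates and the size
#' term breaks ties toward smaller subsets.
#'
#' @param acc Accuracy in `[0, 1]`.
#' @param feasel Number of selected features (`1 <= feasel <= numfea`).
#' @param numfea Total number of features.
#' @param alpha,beta Term weights (`beta = 1 - alpha`).
#' @return The scalar fitness.
#' @examples
#' selection_fitness(0.9558, 12, 44)  # 0.046485
#' @export
selection_fitness <- function(acc, feasel, numfea, alpha = 0.99,
                              beta = 1 - alpha) {
  if (acc < 0 || acc > 1) stop("`acc` must lie in [0, 1]")
  if (feasel < 1 || feasel > numfea)
    stop("`feasel` must lie in [1, numfea]")
  alpha * (1 - acc) + beta * (feasel / numfea)
}

stratified_folds <- function(y, k, seed) {
  idx <- integer(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      pos <- which(y == lv)
      if (length(pos) < k)
        stop("class `", lv, "` has fewer samples (", length(pos),
             ") than cv_folds (", k, "); supply more data or fewer folds")
      idx[pos] <- sample(rep_len(seq_len(k), length(pos)))
    }
  })
  idx
}

#' Stratified cross-validated accuracy of a feature subset
#'
#' Scores a binary feature mask by the pooled accuracy of the configured
#' classifier over stratified k-fold cross-validation restricted to the
#' masked columns. Deterministic given `cfg$cv_seed` and the classifier
#' seed.
#'
#' @param table A `feature_table` (feature columns + `label`).
#' @param mask Logical vector over the feature columns.
#' @param cfg A [fitness_config()].
#' @return Accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(table, mask, cfg = fitness_config()) {
  X <- feature_matrix(table)
  if (length(mask) != ncol(X))
    stop("mask length ", length(mask), " does not match ", ncol(X),
         " feature columns")
  y <- as_label_factor(table$label)
  if (nlevels(y) != 2) stop("expected exactly two classes, got ", nlevels(y))
  folds <- stratified_folds(y, cfg$cv_folds, cfg$cv_seed)
  Xm <- X[, mask, drop = FALSE]
  correct <- 0L
  for (k in seq_len(cfg$cv_folds)) {
    te <- folds == k
    model <- cfg$classifier$fit(Xm[!te, , drop = FALSE], y[!te])
    pred <- cfg$classifier$predict(model, Xm[te, , drop = FALSE])
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Stratified train/test split with min-max normalization
#'
#' Splits a feature table by class at the given ratio (per-class test size
#' `round(n_c * (1 - train_frac))`) and min-max scales every feature to
#' `[0, 1]` using the training minima and maxima only; the same affine map
#' is applied to the test rows. A feature constant in training is scaled
#' to 0 with a warning.
#'
#' @param table A `feature_table`.
#' @param train_frac Training fraction (default 0.6).
#' @param seed Split seed.
#' @return List `train`, `test` (feature tables) and `scaler`
#'   (data frame of per-feature `min`, `max`).
#' @export
split_and_normalize <- function(table, train_frac = 0.6, seed = 1) {
  y <- as_label_factor(table$label)
  if (nlevels(y) < 2) stop("both classes must be present")
  test_idx <- logical(nrow(table))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      pos <- which(y == lv)
      n_test <- round(length(pos) * (1 - train_frac))
      test_idx[sample(pos, n_test)] <- TRUE
    }
  })
  feats <- attr(table, "feature_names") %||% setdiff(names(table), "label")
  train <- table[!test_idx, , drop = FALSE]
  test <- table[test_idx, , drop = FALSE]
  lo <- vapply(train[feats], min, numeric(1))
  hi <- vapply(train[feats], max, numeric(1))
  const <- hi - lo <= 0
  if (any(const))
    warning(sum(const), " feature(s) constant in training scaled to 0: ",
            paste(utils::head(feats[const], 3), collapse = ", "))
  scale_tab <- function(d) {
    for (j in feats) {
      d[[j]] <- if (const[j]) 0 else (d[[j]] - lo[j]) / (hi[j] - lo[j])
    }
    rownames(d) <- NULL
    structure(d, feature_names = feats,
              class = c("feature_table", "data.frame"))
  }
  list(train = scale_tab(train), test = scale_tab(test),
       scaler = data.frame(feature = feats, min = lo, max = hi,
                           row.names = NULL))
}

#' Wrapper feature selection with the whale optimizer
#'
#' Runs [woa_optimize()] over the unit hypercube `[0, 1]^numfea`; each
#' position decodes to a binary mask via [decode_mask()] and is scored by
#' `alpha * (1 - cv_accuracy) + beta * feasel / numfea`. Mask scores are
#' memoized, so re-visited subsets cost nothing. If `test_table` is given,
#' the selected subset is refit on all of `table` and scored once on the
#' held-out rows.
#'
#' @param table Training `feature_table`.
#' @param opt_cfg An [optimizer_config()].
#' @param fit_cfg A [fitness_config()].
#' @param test_table Optional held-out `feature_table`.
#' @return A list of class `"selection_result"`: `mask`, `feasel`,
#'   `selected_features`, `cv_accuracy`, `fitness`, `test_accuracy`
#'   (or `NA`), `convergence_iteration`, `curve`, `eval_count`, `numfea`,
#'   and the two config objects.
#' @export
select_features <- function(table, opt_cfg = optimizer_config(),
                            fit_cfg = fitness_config(),
                            test_table = NULL) {
  feats <- attr(table, "feature_names") %||% setdiff(names(table), "label")
  numfea <- length(feats)
  memo <- new.env(parent = emptyenv())
  score_mask <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    acc <- cv_accuracy(table, bits, fit_cfg)
    out <- list(acc = acc,
                fit = selection_fitness(acc, sum(bits), numfea,
                                        fit_cfg$alpha, fit_cfg$beta))
    memo[[key]] <- out
    out
  }
  fn <- function(pos) score_mask(decode_mask(pos))$fit
  res <- woa_optimize(fn, rep(0, numfea), rep(1, numfea), opt_cfg)
  mask <- decode_mask(res$best_position)
  best <- score_mask(mask)
  test_acc <- NA_real_
  if (!is.null(test_table)) {
    y_tr <- as_label_factor(table$label)
    y_te <- as_label_factor(test_table$label)
    Xtr <- feature_matrix(table)[, mask, drop = FALSE]
    Xte <- feature_matrix(test_table)[, mask, drop = FALSE]
    model <- fit_cfg$classifier$fit(Xtr, y_tr)
    test_acc <- mean(fit_cfg$classifier$predict(model, Xte) == y_te)
  }
  structure(list(mask = mask, feasel = sum(mask),
                 selected_features = feats[mask],
                 cv_accuracy = best$acc, fitness = best$fit,
                 test_accuracy = test_acc,
                 convergence_iteration = res$convergence_iteration,
                 curve = res$convergence_curve,
                 eval_count = res$eval_count, numfea = numfea,
                 opt_cfg = opt_cfg, fit_cfg = fit_cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<feature selection: %d of %d features>\n", x$feasel,
              x$numfea))
  cat(sprintf("  CV accuracy %.4f, fitness %.6f, converged at iter %d\n",
              x$cv_accuracy, x$fitness, x$convergence_iteration))
  if (!is.na(x$test_accuracy))
    cat(sprintf("  held-out accuracy %.4f\n", x$test_accuracy))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
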