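# percentages are rounded half-up (92.745 -> 92.75), matching how the
# evaluation tables in this field are typically printed; base round() is
# round-half-even and would disagree on exact .xx5 values.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Two-class confusion matrix
#'
#' @param true,predicted Vectors of class labels.
#' @param classes Row/column order; defaults to `c("eating", "drinking")`
#'   when those labels are present, otherwise sorted unique labels.
#' @return A 2x2 (or kxk) integer matrix indexed `[true, predicted]`.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (is.null(classes)) {
    classes <- sort(unique(c(true, predicted)))
    if (setequal(classes, c("eating", "drinking")))
      classes <- c("eating", "drinking")
  }
  cm <- table(factor(true, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class and macro classification report
#'
#' From a confusion matrix indexed `[true, predicted]`, computes per-class
#' precision (`TP / column total`), recall (`TP / row total`), and F1 (the
#' harmonic mean of the two), plus overall accuracy (`trace / total`), all
#' as percentages rounded half-up to 2 decimals. The macro row averages
#' the *rounded* per-class percentages (again rounded half-up), mirroring
#' how such summary rows are printed in practice. A class never predicted
#' gets precision 0 and is flagged in the `undefined_precision` attribute.
#'
#' @param cm Square integer matrix `[true, predicted]`.
#' @return A list of class `"class_report"`: `per_class` (data frame with
#'   `precision`, `recall`, `f1` in percent), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `accuracy`, `total`.
#' @examples
#' cm <- matrix(c(458, 14, 21, 298), 2,
#'              dimnames = list(true = c("eating", "drinking"),
#'                              predicted = c("eating", "drinking")))
#' classification_report(cm)
#' @export
classification_report <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  col_tot <- colSums(cm)
  row_tot <- rowSums(cm)
  undef <- col_tot == 0
  precision <- ifelse(undef, 0, tp / ifelse(col_tot == 0, 1, col_tot))
  recall <- ifelse(row_tot == 0, 0, tp / ifelse(row_tot == 0, 1, row_tot))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  pc <- data.frame(precision = round_half_up(100 * precision),
                   recall = round_half_up(100 * recall),
                   f1 = round_half_up(100 * f1),
                   row.names = rownames(cm))
  structure(list(per_class = pc,
                 macro_precision = round_half_up(mean(pc$precision)),
                 macro_recall = round_half_up(mean(pc$recall)),
                 macro_f1 = round_half_up(mean(pc$f1)),
                 accuracy = round_half_up(100 * sum(tp) / total),
                 total = total,
                 undefined_precision = rownames(cm)[undef]),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  print(cbind(x$per_class, accuracy = x$accuracy))
  cat(sprintf("macro: precision %.2f  recall %.2f  F1 %.2f  (n = %d)\n",
              x$macro_precision, x$macro_recall, x$macro_f1, x$total))
  if (length(x$undefined_precision))
    cat("precision undefined (no predictions) for:",
        paste(x$undefined_precision, collapse = ", "), "\n")
  invisible(x)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation between two equal-length
#' vectors, used to quantify pairwise dependence among selected features.
#' All-tied input (zero variance in either argument) returns 0 with a
#' warning, since the tie-corrected denominator vanishes.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("tau-b undefined for all-tied input; returning 0")
    return(0)
  }
  unname(stats::cor(x, y, method = "kendall"))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Grid-approximated maximal information coefficient
#'
#' Approximates the maximal information coefficient: over all grid shapes
#' `k x l` with `k, l >= 2` and `k * l <= max_bins`, both variables are
#' binned by equal-frequency edges, the mutual information of the induced
#' joint histogram is computed, normalized by `log(min(k, l))`, and the
#' maximum over shapes is returned. Because binning is by rank, the score
#' is invariant under strictly monotone transforms of either argument.
#' This is an equal-frequency approximation, not the published
#' dynamic-programming MIC estimator.
#'
#' @param x,y Numeric vectors of equal length `n >= 20`.
#' @param max_bins Grid-size budget `B` (default `floor(n^0.6)`).
#' @return Approximate MIC in `[0, 1]`.
#' @export
mic_grid <- function(x, y, max_bins = floor(length(x)^0.6)) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 20) stop("need at least 20 observations for the MIC grid")
  bin_eq_freq <- function(v, k) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = k + 1),
                                 names = FALSE, type = 7))
    if (length(br) < 3) return(NULL)  # ties collapsed the grid below 2 bins
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  best <- 0
  for (k in 2:max(2, floor(max_bins / 2))) {
    lmax <- floor(max_bins / k)
    if (lmax < 2) break
    bx <- bin_eq_freq(x, k)
    if (is.null(bx)) next
    for (l in 2:lmax) {
      by <- bin_eq_freq(y, l)
      if (is.null(by)) next
      joint <- table(bx, by) / n
      mi <- entropy_nat(rowSums(joint)) + entropy_nat(colSums(joint)) -
        entropy_nat(as.vector(joint))
      score <- mi / log(min(nrow(joint), ncol(joint)))
      if (score > best) best <- score
    }
  }
  min(max(best, 0), 1)
}

#' Permutation feature importance
#'
#' Measures the importance of each selected feature as the mean drop in
#' accuracy on `table` when that feature's column is randomly permuted
#' (breaking its association with the label while preserving its
#' marginal), averaged over `repeats` seeded permutations.
#'
#' @param model A fitted model as returned by a classifier's `fit` (on the
#'   masked training columns).
#' @param classifier The `iwoa_classifier` the model came from.
#' @param table Evaluation `feature_table` (typically held-out rows).
#' @param mask Logical feature mask used when fitting.
#' @param seed Permutation seed.
#' @param repeats Number of permutations per feature (>= 1).
#' @return Named numeric vector of mean accuracy drops, sorted decreasing.
#' @export
permutation_importance <- function(model, classifier, table, mask,
                                   seed = 1, repeats = 10) {
  if (repeats < 1) stop("`repeats` must be >= 1")
  if (is.null(model)) stop("`model` must be a fitted classifier model")
  X <- feature_matrix(table)[, mask, drop = FALSE]
  y <- as_label_factor(table$label)
  base_acc <- mean(classifier$predict(model, X) == y)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        base_acc - mean(classifier$predict(model, Xp) == y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  names(scores) <- colnames(X)
  sort(scores, decreasing = TRUE)
}

#' Drop-one-feature accuracy report
#'
#' Re-evaluates held-out accuracy with each named feature removed from the
#' selected mask (refitting on the training rows each time), to probe
#' whether correlated features are fully substitutable: if accuracy is
#' unchanged without a feature, the rest of the subset carries its
#' information.
#'
#' @param train,test Training and held-out `feature_table`s.
#' @param mask Logical feature mask (the selected subset).
#' @param features_to_drop Character vector of selected feature names; may
#'   be empty.
#' @param cfg A [fitness_config()] supplying the classifier.
#' @return A data frame with columns `feature`, `accuracy`, `delta`
#'   (accuracy minus the full-mask accuracy); the full-mask accuracy is in
#'   attribute `full_accuracy`.
#' @export
drop_one_report <- function(train, test, mask, features_to_drop,
                            cfg = fitness_config()) {
  feats <- attr(train, "feature_names") %||% setdiff(names(train), "label")
  sel <- feats[mask]
  bad <- setdiff(features_to_drop, sel)
  if (length(bad))
    stop("not in the selected mask: ", paste(bad, collapse = ", "))
  y_tr <- as_label_factor(train$label)
  y_te <- as_label_factor(test$label)
  eval_mask <- function(m) {
    model <- cfg$classifier$fit(feature_matrix(train)[, m, drop = FALSE],
                                y_tr)
    mean(cfg$classifier$predict(
      model, feature_matrix(test)[, m, drop = FALSE]) == y_te)
  }
  full_acc <- eval_mask(mask)
  out <- data.frame(feature = character(0), accuracy = numeric(0),
                    delta = numeric(0))
  for (f in features_to_drop) {
    m <- mask & feats != f
    if (!any(m)) stop("cannot drop `", f, "`: it is the last feature")
    acc <- eval_mask(m)
    out <- rbind(out, data.frame(feature = f, accuracy = acc,
                                 delta = acc - full_acc))
  }
  structure(out, full_accuracy = full_acc)
}
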