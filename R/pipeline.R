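#' Full-experiment configuration
#'
#' A single nested configuration for [run_pipeline()] /
#' [run_comparison()]: simulate a recording (or read one), preprocess,
#' extract features, split, select features with the whale optimizer, and
#' evaluate on the held-out rows.
#'
#' @param seed Master seed; per-stage seeds derive from it.
#' @param input Optional path to a sensor CSV; when `NULL` the synthetic
#'   generator is used.
#' @param schedule Bout schedule for the generator (default a short
#'   two-bout demonstration schedule; use [reference_schedule()] for full
#'   study scale).
#' @param fs Sampling rate (Hz).
#' @param filter A [filter_spec()].
#' @param window,overlap Window geometry.
#' @param min_bout_s Short-bout exclusion threshold (seconds).
#' @param train_frac Training fraction of the stratified split.
#' @param opt An [optimizer_config()].
#' @param fit A [fitness_config()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, input = NULL,
                            schedule = data.frame(
                              label = rep(c("eating", "drinking"), 4),
                              duration_s = rep(c(60, 40), 4)),
                            fs = 5,
                            filter = filter_spec(fs = fs),
                            window = 14, overlap = 0.5, min_bout_s = 3,
                            train_frac = 0.6,
                            opt = optimizer_config(seed = seed),
                            fit = fitness_config(cv_seed = seed)) {
  structure(list(seed = as.integer(seed), input = input,
                 schedule = schedule, fs = fs, filter = filter,
                 window = window, overlap = overlap,
                 min_bout_s = min_bout_s, train_frac = train_frac,
                 opt = opt, fit = fit),
            class = "pipeline_config")
}

preprocess_recording <- function(rec, cfg) {
  acc <- resultant_magnitude(rec, "acceleration")
  gyr <- resultant_magnitude(rec, "angular_velocity")
  if (!is.null(acc$label)) {
    acc <- exclude_short_bouts(acc, cfg$min_bout_s)
    gyr <- exclude_short_bouts(gyr, cfg$min_bout_s)
  }
  acc <- lowpass_filter(acc, cfg$filter)
  gyr <- lowpass_filter(gyr, cfg$filter)
  list(acc = acc, gyr = gyr)
}

#' Run the full selection experiment
#'
#' Executes simulate (or load) -> preprocess -> extract -> split ->
#' select -> evaluate, optionally writing every stage artifact under
#' `out_dir`, and returns a run manifest. Identical config and seeds give
#' identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `"run_manifest"`: `config`, `seeds`,
#'   `versions`, `paths`, `selection` (a `selection_result`), `report`
#'   (a `class_report` on the held-out rows), `baseline_test_accuracy`
#'   (all 44 features, held-out), `n_windows`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("input file not found: ", cfg$input)
  rec <- if (is.null(cfg$input))
    simulate_recording(cfg$schedule, fs = cfg$fs, seed = cfg$seed)
  else
    read_sensor_csv(cfg$input, fs = cfg$fs)
  pre <- preprocess_recording(rec, cfg)
  tab <- build_feature_table(pre$acc, pre$gyr, size = cfg$window,
                             overlap = cfg$overlap)
  sp <- split_and_normalize(tab, train_frac = cfg$train_frac,
                            seed = cfg$seed)
  sel <- select_features(sp$train, cfg$opt, cfg$fit, test_table = sp$test)
  # baseline: all features, same classifier, same held-out rows
  y_tr <- as_label_factor(sp$train$label)
  y_te <- as_label_factor(sp$test$label)
  full_mask <- rep(TRUE, sel$numfea)
  model <- cfg$fit$classifier$fit(feature_matrix(sp$train), y_tr)
  pred_full <- cfg$fit$classifier$predict(model, feature_matrix(sp$test))
  baseline_acc <- mean(pred_full == y_te)
  model_sel <- cfg$fit$classifier$fit(
    feature_matrix(sp$train)[, sel$mask, drop = FALSE], y_tr)
  pred_sel <- cfg$fit$classifier$predict(
    model_sel, feature_matrix(sp$test)[, sel$mask, drop = FALSE])
  cm <- confusion_matrix(as.character(y_te), as.character(pred_sel))
  report <- classification_report(cm)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_feature_csv(tab, p("features.csv"))
    jsonlite::write_json(
      list(mask = as.integer(sel$mask),
           selected_features = sel$selected_features,
           cv_accuracy = sel$cv_accuracy, fitness = sel$fitness,
           test_accuracy = sel$test_accuracy,
           convergence_iteration = sel$convergence_iteration,
           curve = sel$curve),
      p("selection.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(confusion = cm, per_class = report$per_class,
           accuracy = report$accuracy,
           macro_precision = report$macro_precision,
           macro_recall = report$macro_recall,
           macro_f1 = report$macro_f1,
           baseline_test_accuracy = baseline_acc),
      p("report.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(features = p("features.csv"),
               selection = p("selection.json"), report = p("report.json"))
    stopifnot(all(file.exists(paths)))
  }
  structure(list(config = cfg,
                 seeds = c(master = cfg$seed, optimizer = cfg$opt$seed,
                           cv = cfg$fit$cv_seed),
                 versions = c(iwoaselect =
                                as.character(utils::packageVersion("iwoaselect")),
                              R = paste(R.version$major, R.version$minor,
                                        sep = ".")),
                 paths = paths, selection = sel, report = report,
                 confusion = cm,
                 baseline_test_accuracy = baseline_acc,
                 n_windows = nrow(tab)),
            class = "run_manifest")
}

#' Compare optimizer variants over repeated seeded runs
#'
#' Runs each variant over the same feature table and seed list and
#' summarizes per-run held-out accuracy, fitness, convergence iteration
#' and subset size as max / min / ave rows per variant.
#'
#' @param table A `feature_table` (pre-split training data is built per
#'   seed inside).
#' @param variants Character vector of optimizer variants (>= 2 to
#'   compare; must be a subset of `c("woa", "iwoa")`).
#' @param seeds Integer vector of run seeds.
#' @param fit_cfg A [fitness_config()].
#' @param pop_size,max_iter Optimizer budget per run.
#' @param train_frac Stratified split fraction per run.
#' @return A list of class `"comparison_report"`: `runs` (one row per
#'   variant x seed) and `summary` (max/min/ave per variant).
#' @export
run_comparison <- function(table, variants = c("woa", "iwoa"),
                           seeds = 1:20, fit_cfg = fitness_config(),
                           pop_size = 15, max_iter = 50,
                           train_frac = 0.6) {
  bad <- setdiff(variants, c("woa", "iwoa"))
  if (length(bad))
    stop("unknown variant(s): ", paste(bad, collapse = ", "),
         "; available: woa, iwoa")
  if (length(variants) < 2) stop("need at least 2 variants to compare")
  runs <- do.call(rbind, lapply(variants, function(v) {
    do.call(rbind, lapply(seeds, function(s) {
      sp <- split_and_normalize(table, train_frac = train_frac, seed = s)
      cfg <- optimizer_config(pop_size = pop_size, max_iter = max_iter,
                              variant = v, seed = s)
      sel <- select_features(sp$train, cfg, fit_cfg, test_table = sp$test)
      data.frame(variant = v, seed = s,
                 accuracy = sel$test_accuracy, fitness = sel$fitness,
                 convergence_iteration = sel$convergence_iteration,
                 feature_size = sel$feasel)
    }))
  }))
  summ <- do.call(rbind, lapply(variants, function(v) {
    r <- runs[runs$variant == v, ]
    data.frame(variant = v, statistic = c("max", "min", "ave"),
               accuracy = c(max(r$accuracy), min(r$accuracy),
                            mean(r$accuracy)),
               fitness = c(max(r$fitness), min(r$fitness),
                           mean(r$fitness)),
               convergence_iteration = c(max(r$convergence_iteration),
                                         min(r$convergence_iteration),
                                         mean(r$convergence_iteration)),
               feature_size = c(max(r$feature_size), min(r$feature_size),
                                mean(r$feature_size)))
  }))
  structure(list(runs = runs, summary = summ),
            class = "comparison_report")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<pipeline run>\n")
  cat(sprintf("  %d windows; selected %d/%d features\n", x$n_windows,
              x$selection$feasel, x$selection$numfea))
  cat(sprintf("  held-out accuracy %.2f%% (all-feature baseline %.2f%%)\n",
              x$report$accuracy, 100 * x$baseline_test_accuracy))
  invisible(x)
}
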