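#' Behavior signal specification
#'
#' Parameters of one simulated behavior class. Acceleration is modeled as
#' a shared baseline plus an amplitude-modulated burst train (a duty-cycled
#' oscillation, emulating head pecks or sip strokes) plus Gaussian noise;
#' angular velocity as a baseline plus a slower sinusoidal head cycle plus
#' noise.
#'
#' @param name `"eating"` or `"drinking"`.
#' @param base_level Resultant acceleration baseline (g).
#' @param burst_rate_hz,burst_amplitude,burst_duty Burst train rate (must
#'   stay below the Nyquist frequency), amplitude (g) and duty fraction
#'   for the acceleration channel.
#' @param cycle_rate_hz,cycle_amplitude Sinusoidal cycle rate and
#'   amplitude (deg/s) for the angular-velocity channel.
#' @param noise_sd Acceleration noise standard deviation (g).
#' @param gyr_base,gyr_noise_sd Angular-velocity baseline and noise
#'   (deg/s).
#' @return A list of class `"behavior_spec"`.
#' @export
behavior_spec <- function(name, base_level = 1.0, burst_rate_hz = 2.0,
                          burst_amplitude = 0.5, burst_duty = 0.5,
                          cycle_rate_hz = 1.0, cycle_amplitude = 30,
                          noise_sd = 0.1, gyr_base = 20,
                          gyr_noise_sd = 10 * noise_sd) {
  if (burst_amplitude < 0 || cycle_amplitude < 0)
    stop("amplitudes must be >= 0")
  structure(list(name = name, base_level = base_level,
                 burst_rate_hz = burst_rate_hz,
                 burst_amplitude = burst_amplitude, burst_duty = burst_duty,
                 cycle_rate_hz = cycle_rate_hz,
                 cycle_amplitude = cycle_amplitude, noise_sd = noise_sd,
                 gyr_base = gyr_base, gyr_noise_sd = gyr_noise_sd),
            class = "behavior_spec")
}

#' Default behavior specifications
#'
#' Frozen defaults for the two simulated behaviors. Feeding is bursty:
#' fast pecking strokes (2.2 Hz, high amplitude, short duty) on the
#' acceleration channel with vigorous head rotation. Drinking is slower
#' and smoother: sipping cycles near 0.5 Hz with lower amplitude. The
#' noise levels and amplitudes are chosen so the two classes'
#' resultant-magnitude distributions overlap while the windowed
#' 44-feature representation remains separable.
#'
#' @return Named list with elements `eating` and `drinking`.
#' @export
default_behavior_specs <- function() {
  list(
    eating = behavior_spec("eating", base_level = 1.0, burst_rate_hz = 2.2,
                           burst_amplitude = 0.65, burst_duty = 0.45,
                           cycle_rate_hz = 1.8, cycle_amplitude = 55,
                           noise_sd = 0.12, gyr_base = 25,
                           gyr_noise_sd = 12),
    drinking = behavior_spec("drinking", base_level = 1.0,
                             burst_rate_hz = 0.5, burst_amplitude = 0.35,
                             burst_duty = 0.6, cycle_rate_hz = 0.5,
                             cycle_amplitude = 28, noise_sd = 0.10,
                             gyr_base = 22, gyr_noise_sd = 9)
  )
}

#' Simulate a labeled nine-axis sensor recording
#'
#' Generates a triaxial acceleration + angular-velocity recording from a
#' bout schedule: for each bout the named behavior's signal model is
#' sampled at `fs` Hz and labeled per sample. Fully reproducible under
#' `seed`.
#'
#' @param schedule Data frame with columns `label` and `duration_s`
#'   (bout durations in seconds, >= 0).
#' @param specs Named list of [behavior_spec()]s covering every label in
#'   the schedule.
#' @param fs Sampling rate in Hz (default 5).
#' @param seed Integer seed.
#' @return A [triaxial_series()] with per-sample labels.
#' @export
simulate_recording <- function(schedule, specs = default_behavior_specs(),
                               fs = 5, seed = 1) {
  stopifnot(is.data.frame(schedule),
            all(c("label", "duration_s") %in% names(schedule)))
  if (any(schedule$duration_s < 0)) stop("bout durations must be >= 0")
  miss <- setdiff(unique(schedule$label), names(specs))
  if (length(miss))
    stop("no behavior_spec for label(s): ", paste(miss, collapse = ", "))
  for (sp in specs)
    if (sp$burst_rate_hz >= fs / 2 || sp$cycle_rate_hz >= fs / 2)
      stop("behavior `", sp$name, "` has a rate at or above Nyquist (",
           fs / 2, " Hz)")
  withr::with_seed(seed, {
    ax <- ay <- az <- jx <- jy <- jz <- numeric(0)
    label <- character(0)
    t_off <- 0
    for (i in seq_len(nrow(schedule))) {
      sp <- specs[[schedule$label[i]]]
      n <- round(schedule$duration_s[i] * fs)
      if (n == 0) next
      tt <- t_off + seq.int(0, n - 1) / fs
      # duty-gated oscillation: active fraction `burst_duty` of each cycle
      phase <- (tt * sp$burst_rate_hz) %% 1
      burst <- sp$burst_amplitude * (phase < sp$burst_duty) *
        sin(2 * pi * tt * sp$burst_rate_hz)
      b3 <- sp$base_level / sqrt(3)
      ax <- c(ax, b3 + 0.6 * burst + stats::rnorm(n, 0, sp$noise_sd))
      ay <- c(ay, b3 + 0.3 * burst + stats::rnorm(n, 0, sp$noise_sd))
      az <- c(az, b3 + 0.8 * burst + stats::rnorm(n, 0, sp$noise_sd))
      cyc <- sp$cycle_amplitude * sin(2 * pi * tt * sp$cycle_rate_hz)
      g3 <- sp$gyr_base / sqrt(3)
      jx <- c(jx, g3 + 0.7 * cyc + stats::rnorm(n, 0, sp$gyr_noise_sd))
      jy <- c(jy, g3 + 0.4 * cyc + stats::rnorm(n, 0, sp$gyr_noise_sd))
      jz <- c(jz, g3 + 0.2 * cyc + stats::rnorm(n, 0, sp$gyr_noise_sd))
      label <- c(label, rep(schedule$label[i], n))
      t_off <- t_off + n / fs
    }
    triaxial_series(ax, ay, az, jx, jy, jz, label = label, fs = fs)
  })
}

#' Reference bout schedule at full study scale
#'
#' One long feeding bout (8380 samples at 5 Hz) followed by one drinking
#' bout (5460 samples): with window size 14 and 50% overlap,
#' majority-vote windowing of the concatenated recording yields exactly
#' 1197 feeding windows and 779 drinking windows (1976 rows), the scale at
#' which the full pipeline is exercised.
#'
#' @return A schedule data frame for [simulate_recording()].
#' @export
reference_schedule <- function() {
  data.frame(label = c("eating", "drinking"),
             duration_s = c(8380 / 5, 5460 / 5))
}

#' Synthetic feature-table specification
#'
#' @param n_per_class Rows per class.
#' @param k_informative,k_redundant,k_noise Counts of class-informative
#'   features (class-shifted Gaussians), redundant features (noisy copies
#'   of informative ones) and pure-noise features; `d` is their sum.
#' @param effect_size Standardized mean shift of informative features
#'   between classes.
#' @param redundancy_noise_sd Noise added to redundant copies.
#' @param seed Integer seed.
#' @return A list of class `"table_spec"`.
#' @export
table_spec <- function(n_per_class = 100, k_informative = 5,
                       k_redundant = 10, k_noise = 15, effect_size = 1,
                       redundancy_noise_sd = 0.1, seed = 1) {
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  structure(list(n_per_class = n_per_class, k_informative = k_informative,
                 k_redundant = k_redundant, k_noise = k_noise,
                 d = k_informative + k_redundant + k_noise,
                 effect_size = effect_size,
                 redundancy_noise_sd = redundancy_noise_sd,
                 seed = as.integer(seed)),
            class = "table_spec")
}

#' Generate a feature table with known informative structure
#'
#' Builds a two-class table for parameter-recovery experiments:
#' informative features are unit-variance Gaussians whose class means
#' differ by `effect_size`; redundant features are informative columns
#' plus `N(0, redundancy_noise_sd)` noise (parents assigned round-robin);
#' noise features are standard Gaussians independent of the class. The
#' ground-truth informative mask is returned for recovery scoring.
#'
#' @param spec A [table_spec()].
#' @return List `table` (a `feature_table` with labels `eating` /
#'   `drinking`), `truth` (logical mask of the informative features),
#'   `parents` (parent index per redundant feature, `NA` otherwise).
#' @export
make_table <- function(spec = table_spec()) {
  stopifnot(inherits(spec, "table_spec"))
  n <- 2 * spec$n_per_class
  y <- rep(c("eating", "drinking"), each = spec$n_per_class)
  shift <- ifelse(y == "eating", spec$effect_size / 2,
                  -spec$effect_size / 2)
  withr::with_seed(spec$seed, {
    X <- matrix(NA_real_, n, spec$d)
    for (j in seq_len(spec$k_informative))
      X[, j] <- stats::rnorm(n, mean = shift)
    parents <- rep(NA_integer_, spec$d)
    if (spec$k_redundant > 0) {
      for (r in seq_len(spec$k_redundant)) {
        j <- spec$k_informative + r
        p <- ((r - 1) %% spec$k_informative) + 1
        parents[j] <- p
        X[, j] <- X[, p] + stats::rnorm(n, 0, spec$redundancy_noise_sd)
      }
    }
    if (spec$k_noise > 0) {
      jj <- (spec$d - spec$k_noise + 1):spec$d
      X[, jj] <- stats::rnorm(n * spec$k_noise)
    }
  })
  nm <- c(sprintf("inf_%02d", seq_len(spec$k_informative)),
          if (spec$k_redundant > 0)
            sprintf("red_%02d", seq_len(spec$k_redundant)),
          if (spec$k_noise > 0)
            sprintf("noise_%02d", seq_len(spec$k_noise)))
  tab <- as.data.frame(X)
  names(tab) <- nm
  tab$label <- y
  tab <- structure(tab, feature_names = nm,
                   class = c("feature_table", "data.frame"))
  truth <- seq_len(spec$d) <= spec$k_informative
  list(table = tab, truth = truth, parents = parents)
}

#' Recovery scores of a selected mask against the ground truth
#'
#' @param selected,truth Equal-length logical masks.
#' @return Named numeric vector: `jaccard` (intersection over union) and
#'   `recall_informative` (fraction of true informative features
#'   selected).
#' @export
recovery_score <- function(selected, truth) {
  if (length(selected) != length(truth))
    stop("masks must have equal length")
  inter <- sum(selected & truth)
  uni <- sum(selected | truth)
  c(jaccard = if (uni == 0) 1 else inter / uni,
    recall_informative = if (sum(truth) == 0) 1 else inter / sum(truth))
}

#' Bhattacharyya coefficient of two samples
#'
#' Histogram-based overlap of two empirical distributions on a shared
#' grid; 0 means disjoint support, 1 identical distributions. Used to
#' check that the two behaviors' resultant-magnitude ranges genuinely
#' overlap.
#'
#' @param x,y Numeric samples.
#' @param bins Number of shared histogram bins.
#' @return Coefficient in `[0, 1]`.
#' @export
bhattacharyya_coefficient <- function(x, y, bins = 30) {
  rng <- range(c(x, y))
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  px <- graphics::hist(x, breaks = br, plot = FALSE)$counts / length(x)
  py <- graphics::hist(y, breaks = br, plot = FALSE)$counts / length(y)
  sum(sqrt(px * py))
}
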