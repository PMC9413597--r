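# Independent oracles used across tests.

# brute-force O(n^2) Kendall tau-b pair counting
tau_brute <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  nx <- n0 - sum(choose(table(x), 2)) # pairs untied in x
  ny <- n0 - sum(choose(table(y), 2))
  (C - D) / sqrt(nx * ny)
}

# brute-force window start enumeration
count_windows_brute <- function(n, size, step) {
  starts <- 0
  count <- 0
  while (starts + size <= n) {
    count <- count + 1
    starts <- starts + step
  }
  count
}

# steady-state amplitude of a filtered sinusoid by sin/cos regression over
# the middle of the series
measured_amplitude <- function(f, fs, spec, dur = 60) {
  t <- seq(0, dur, by = 1 / fs)
  y <- lowpass_filter(sin(2 * pi * f * t), spec)
  i <- seq(round(length(y) * 0.4), round(length(y) * 0.9))
  co <- stats::coef(stats::lm(y[i] ~ sin(2 * pi * f * t[i]) +
                                cos(2 * pi * f * t[i])))
  unname(sqrt(co[2]^2 + co[3]^2))
}

# analog Butterworth prototype gain and its bilinear (implemented) version
butter_gain_analog <- function(f, fc, n = 8) (1 + (f / fc)^(2 * n))^(-0.5)
butter_gain_digital <- function(f, fs, fc, n = 8)
  (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * n))^(-0.5)

# small labeled recording for plumbing tests
tiny_recording <- function(seed = 1, eat_s = 60, drink_s = 40, bouts = 2) {
  simulate_recording(
    data.frame(label = rep(c("eating", "drinking"), bouts),
               duration_s = rep(c(eat_s, drink_s), bouts)),
    fs = 5, seed = seed)
}

tiny_feature_table <- function(seed = 1, ...) {
  rec <- tiny_recording(seed = seed, ...)
  acc <- lowpass_filter(resultant_magnitude(rec, "acceleration"),
                        filter_spec(fs = 5))
  gyr <- lowpass_filter(resultant_magnitude(rec, "angular_velocity"),
                        filter_spec(fs = 5))
  build_feature_table(acc, gyr)
}

# frozen recovery-benchmark conditions
recovery_table_spec <- function() {
  table_spec(n_per_class = 120, k_informative = 5, k_redundant = 10,
             k_noise = 15, effect_size = 1.2, redundancy_noise_sd = 0.6,
             seed = 7)
}

lda_fitness <- function(cv_seed = 1)
  fitness_config(classifier = "lda", cv_seed = cv_seed)
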