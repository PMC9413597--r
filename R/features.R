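time_feature_names <- c("mean", "over_mean_count", "upper_quartile",
                        "lower_quartile", "iqr", "variance", "std", "max",
                        "min", "range", "mode")
freq_feature_names <- c("dc", "amp_mean", "amp_variance", "amp_std",
                        "amp_skew", "amp_kurtosis", "shape_mean",
                        "shape_variance", "shape_std", "shape_skew",
                        "shape_kurtosis")

#' Canonical names of the 44 window features
#'
#' 22 features per resultant signal (11 time-domain + 11 frequency-domain),
#' for the resultant acceleration (`acc_`) and the resultant angular
#' velocity (`gyr_`), in the fixed extraction order: acc time, acc
#' frequency, gyr time, gyr frequency.
#'
#' @return Character vector of length 44.
#' @export
feature_names <- function() {
  c(paste0("acc_", c(time_feature_names, freq_feature_names)),
    paste0("gyr_", c(time_feature_names, freq_feature_names)))
}

# skewness (m3/m2^1.5) and excess kurtosis (m4/m2^2 - 3) from population
# central moments; zero-variance input maps to 0 by convention.
moment_shape_stats <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 1e-24 * max(1, m^2)) return(c(skew = 0, kurt = 0))
  c(skew = mean((x - m)^3) / m2^1.5,
    kurt = mean((x - m)^4) / m2^2 - 3)
}

#' Time-domain features of one window
#'
#' The 11 time-domain descriptors of a windowed magnitude signal: mean,
#' number of over-mean points (strictly above the window mean), upper and
#' lower quartiles (linear-interpolation quantiles), interquartile range,
#' population variance, standard deviation, maximum, minimum, range
#' (max minus min), and mode (most frequent value after rounding to
#' `mode_digits` decimals, ties broken toward the smallest value).
#'
#' @param x Numeric window, length >= 2.
#' @param mode_digits Decimals used to bin values before the mode count.
#' @return Named numeric vector of length 11.
#' @export
time_domain_features <- function(x, mode_digits = 2) {
  if (length(x) < 2) stop("window must have length >= 2")
  m <- mean(x)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  v <- mean((x - m)^2)  # population variance
  xr <- round(x, mode_digits)
  tab <- table(xr)
  vals <- as.numeric(names(tab))
  mode_val <- min(vals[tab == max(tab)])
  c(mean = m,
    over_mean_count = sum(x > m),
    upper_quartile = q[2],
    lower_quartile = q[1],
    iqr = q[2] - q[1],
    variance = v,
    std = sqrt(v),
    max = max(x),
    min = min(x),
    range = max(x) - min(x),
    mode = mode_val)
}

#' Frequency-domain features of one window
#'
#' Computes the DFT of the window and summarizes its DC-exclusive half
#' spectrum two ways. The direct current is `|X_0|/N`, equal to the window
#' mean for real input. Amplitude statistics are the sample mean, variance
#' (denominator `K - 1`), standard deviation, skewness and excess kurtosis
#' of the amplitudes `A_k = |X_k|, k = 1..floor(N/2)`. Shape statistics
#' treat `p_k = A_k / sum(A)` as a probability mass over the bin
#' frequencies `f_k = k * fs / N`: the spectral centroid, its variance and
#' standard deviation, and its standardized skewness and excess kurtosis.
#' A zero spectrum yields all-zero shape statistics.
#'
#' @param x Numeric window, length >= 4.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 11.
#' @export
frequency_domain_features <- function(x, fs) {
  n <- length(x)
  if (n < 4) stop("window must have length >= 4 (too few spectral bins)")
  X <- stats::fft(x)
  dc <- Mod(X[1]) / n
  K <- n %/% 2
  A <- Mod(X[2:(K + 1)])
  scale_ref <- max(Mod(X)) / n
  if (max(A) <= 1e-10 * max(1, scale_ref)) {
    amp <- c(amp_mean = 0, amp_variance = 0, amp_std = 0, amp_skew = 0,
             amp_kurtosis = 0)
    shp <- c(shape_mean = 0, shape_variance = 0, shape_std = 0,
             shape_skew = 0, shape_kurtosis = 0)
    return(c(dc = dc, amp, shp))
  }
  av <- stats::var(A)
  sk <- moment_shape_stats(A)
  amp <- c(amp_mean = mean(A), amp_variance = av, amp_std = sqrt(av),
           amp_skew = sk[["skew"]], amp_kurtosis = sk[["kurt"]])
  p <- A / sum(A)
  f <- (1:K) * fs / n
  mu <- sum(f * p)
  m2 <- sum((f - mu)^2 * p)
  if (m2 <= 1e-18 * max(1, mu^2)) {
    shp <- c(shape_mean = mu, shape_variance = 0, shape_std = 0,
             shape_skew = 0, shape_kurtosis = 0)
  } else {
    shp <- c(shape_mean = mu, shape_variance = m2, shape_std = sqrt(m2),
             shape_skew = sum((f - mu)^3 * p) / m2^1.5,
             shape_kurtosis = sum((f - mu)^4 * p) / m2^2 - 3)
  }
  c(dc = dc, amp, shp)
}

#' Full 44-dimensional feature vector of a window pair
#'
#' Concatenates the time- and frequency-domain features of an
#' acceleration-magnitude window and the co-indexed angular-velocity
#' window in the fixed order `acc` time (11), `acc` frequency (11),
#' `gyr` time (11), `gyr` frequency (11).
#'
#' @param acc_window,gyr_window Equal-length numeric windows.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 44 (names from
#'   [feature_names()]).
#' @export
window_features <- function(acc_window, gyr_window, fs) {
  if (length(acc_window) != length(gyr_window))
    stop("acceleration and angular-velocity windows must have equal length")
  out <- c(time_domain_features(acc_window),
           frequency_domain_features(acc_window, fs),
           time_domain_features(gyr_window),
           frequency_domain_features(gyr_window, fs))
  names(out) <- feature_names()
  out
}

#' Build a labeled feature table from aligned resultant series
#'
#' Windows both resultant series with identical geometry and extracts one
#' 44-feature row per co-indexed window pair, ordered by window start
#' index. Window labels come from the acceleration series' majority vote;
#' windows without a label are dropped with a warning.
#'
#' @param acc,gyr Aligned `resultant_series` of equal length (acceleration
#'   and angular-velocity magnitudes).
#' @param size,overlap Window geometry, see [segment_windows()].
#' @return A data frame of class `"feature_table"`: 44 feature columns plus
#'   a `label` column, attribute `feature_names`.
#' @export
build_feature_table <- function(acc, gyr, size = 14, overlap = 0.5) {
  if (nrow(acc) != nrow(gyr))
    stop("acceleration and angular-velocity series must be aligned ",
         "(equal length)")
  fs <- attr(acc, "fs")
  wa <- segment_windows(acc, size = size, overlap = overlap)
  wg <- segment_windows(gyr, size = size, overlap = overlap)
  nw <- length(wa$starts)
  if (nw == 0L) {
    tab <- as.data.frame(matrix(numeric(0), 0, 44,
                                dimnames = list(NULL, feature_names())))
    tab$label <- character(0)
    return(structure(tab, feature_names = feature_names(),
                     class = c("feature_table", "data.frame")))
  }
  rows <- t(vapply(seq_len(nw), function(i)
    window_features(wa$values[i, ], wg$values[i, ], fs), numeric(44)))
  tab <- as.data.frame(rows)
  names(tab) <- feature_names()
  tab$label <- if (is.null(wa$labels)) NA_character_ else wa$labels
  drop <- is.na(tab$label)
  if (any(drop)) {
    warning(sum(drop), " window(s) without a label dropped")
    tab <- tab[!drop, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, feature_names = feature_names(),
            class = c("feature_table", "data.frame"))
}

#' Read / write feature tables
#'
#' Feature tables are stored as headered CSV with the 44 canonical feature
#' columns plus `label`.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(d)) stop("feature CSV must have a `label` column")
  feats <- setdiff(names(d), "label")
  structure(d, feature_names = feats,
            class = c("feature_table", "data.frame"))
}

feature_matrix <- function(table) {
  feats <- attr(table, "feature_names")
  if (is.null(feats)) feats <- setdiff(names(table), "label")
  as.matrix(table[, feats, drop = FALSE])
}
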