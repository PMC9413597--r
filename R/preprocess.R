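#' Construct a triaxial inertial series
#'
#' Bundles time-stamped triaxial acceleration and triaxial angular-velocity
#' samples from a neck-mounted nine-axis inertial sensor into a validated
#' data frame. All six channels must have equal length and the timestamps
#' must be uniform at rate `fs`.
#'
#' @param t Timestamps in seconds, strictly increasing with constant step
#'   `1/fs`. If `NULL`, generated as `(0:(n-1))/fs`.
#' @param ax,ay,az Per-axis acceleration (sensor units, nominally g).
#' @param jx,jy,jz Per-axis angular velocity (deg/s).
#' @param label Optional per-sample behavior tag (e.g. `"eating"`,
#'   `"drinking"`); `NULL` for unlabeled streams.
#' @param fs Sampling rate in Hz (default 5, the sensor's collection
#'   frequency).
#' @return A data frame of class `"triaxial_series"` with columns
#'   `t, ax, ay, az, jx, jy, jz` (and `label` if given) and attribute `fs`.
#' @examples
#' ts <- triaxial_series(ax = c(3, 0), ay = c(4, 0), az = c(12, 0),
#'                       jx = 0, jy = 0, jz = 0, fs = 5)
#' resultant_magnitude(ts, "acceleration")$value
#' @export
triaxial_series <- function(ax, ay, az, jx, jy, jz, t = NULL, label = NULL,
                            fs = 5) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  n <- length(ax)
  chans <- list(ax = ax, ay = ay, az = az, jx = jx, jy = jy, jz = jz)
  chans <- lapply(chans, function(x) if (length(x) == 1L) rep(x, n) else x)
  lens <- vapply(chans, length, integer(1))
  if (any(lens != n))
    stop("all six channels must have equal length; got lengths ",
         paste(lens, collapse = ", "))
  if (is.null(t)) {
    t <- seq.int(0L, n - 1L) / fs
  } else {
    if (length(t) != n) stop("`t` must match the channel length")
    if (n > 1) {
      dt <- diff(t)
      if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6 / fs)
        stop("timestamps must be strictly increasing with constant step 1/fs")
    }
  }
  out <- data.frame(t = t, chans)
  if (!is.null(label)) {
    if (length(label) == 1L) label <- rep(label, n)
    if (length(label) != n) stop("`label` must match the channel length")
    out$label <- as.character(label)
  }
  structure(out, fs = fs, class = c("triaxial_series", "data.frame"))
}

#' Read a sensor CSV
#'
#' Reads a headered CSV with columns `t,ax,ay,az,jx,jy,jz[,label]` into a
#' [triaxial_series()].
#'
#' @param path CSV path.
#' @param fs Sampling rate in Hz; if `NULL`, inferred from the median
#'   timestamp step.
#' @return A `triaxial_series`.
#' @export
read_sensor_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "ax", "ay", "az", "jx", "jy", "jz")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sensor CSV is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(fs)) {
    if (nrow(d) < 2) stop("cannot infer `fs` from fewer than 2 samples")
    fs <- 1 / stats::median(diff(d$t))
  }
  triaxial_series(d$ax, d$ay, d$az, d$jx, d$jy, d$jz, t = d$t,
                  label = if ("label" %in% names(d)) d$label else NULL,
                  fs = fs)
}

new_resultant_series <- function(t, value, label, channel, fs) {
  out <- data.frame(t = t, value = value)
  if (!is.null(label)) out$label <- as.character(label)
  structure(out, channel = channel, fs = fs,
            class = c("resultant_series", "data.frame"))
}

#' Resultant magnitude of a triaxial channel
#'
#' Collapses the three axes of either the acceleration or angular-velocity
#' channel into a single nonnegative magnitude series,
#' `sqrt(x^2 + y^2 + z^2)` per sample. Orientation information is discarded;
#' the magnitude is what the downstream feature extractor consumes.
#'
#' @param series A [triaxial_series()].
#' @param channel `"acceleration"` (axes ax, ay, az) or
#'   `"angular_velocity"` (axes jx, jy, jz).
#' @return A data frame of class `"resultant_series"` with columns
#'   `t, value` (and `label` if present), attributes `channel` and `fs`.
#' @export
resultant_magnitude <- function(series,
                                channel = c("acceleration",
                                            "angular_velocity")) {
  channel <- match.arg(channel)
  stopifnot(inherits(series, "triaxial_series"))
  cols <- if (channel == "acceleration") c("ax", "ay", "az")
          else c("jx", "jy", "jz")
  v <- sqrt(series[[cols[1]]]^2 + series[[cols[2]]]^2 + series[[cols[3]]]^2)
  new_resultant_series(series$t, v, series$label, channel, attr(series, "fs"))
}

#' Butterworth low-pass filter specification
#'
#' @param order Filter order (default 8).
#' @param cutoff_hz Cutoff frequency in Hz; must lie strictly below the
#'   Nyquist frequency `fs/2`. Default 1 Hz at the 5 Hz sensor rate.
#' @param fs Sampling rate in Hz.
#' @param mode `"zero_phase"` (forward-backward, no phase lag, squares the
#'   magnitude response) or `"causal"` (single forward pass).
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(order = 8, cutoff_hz = 1.0, fs = 5,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (order < 1 || order != round(order)) stop("`order` must be an integer >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("`cutoff_hz` must satisfy 0 < cutoff_hz < fs/2 = ", fs / 2, " Hz")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz, fs = fs,
                 mode = mode), class = "filter_spec")
}

#' Low-pass filter a resultant series
#'
#' Applies a Butterworth low-pass filter (unit DC gain) to remove
#' high-frequency sensor noise from a resultant-magnitude series before
#' windowing. The default is an 8th-order filter applied forward-backward
#' (zero phase), so window labels stay aligned with the motion that
#' produced them.
#'
#' @param series A `resultant_series` (or bare numeric vector).
#' @param spec A [filter_spec()]; its `fs` must match the series.
#' @return The filtered series, same class and length as the input.
#' @export
lowpass_filter <- function(series, spec = filter_spec(fs = attr(series, "fs"))) {
  stopifnot(inherits(spec, "filter_spec"))
  x <- if (is.numeric(series)) series else series$value
  minlen <- 3L * spec$order + 1L
  if (length(x) < minlen)
    stop("series too short to filter: need at least ", minlen,
         " samples for an order-", spec$order, " filter, got ", length(x))
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$fs / 2),
                       type = "low")
  if (spec$mode == "zero_phase") {
    # forward-backward pass with constant-hold padding long enough for the
    # slowest pole's transient to decay below 1e-13, so edges are clean
    # (a bare double pass distorts both ends badly)
    p_max <- max(Mod(polyroot(rev(bf$a))))
    pad <- as.integer(min(5000, max(50, ceiling(log(1e-13) / log(p_max)))))
    n <- length(x)
    xe <- c(rep(x[1], pad), x, rep(x[n], pad))
    yf <- as.numeric(signal::filter(bf, xe))
    yb <- rev(as.numeric(signal::filter(bf, rev(yf))))
    y <- yb[(pad + 1):(pad + n)]
  } else {
    y <- as.numeric(signal::filter(bf, x))
  }
  if (is.numeric(series)) return(y)
  out <- series
  out$value <- y
  out
}

#' Segment a series into overlapping sliding windows
#'
#' Cuts a series into fixed-length windows starting at
#' `0, step, 2*step, ...` (0-based) with
#' `step = round(size * (1 - overlap))`; a trailing partial window is
#' discarded. Each window's label is the majority vote of its per-sample
#' labels, ties broken toward the label appearing earlier in the window.
#'
#' @param series A `resultant_series` or numeric vector.
#' @param size Window length in samples (default 14).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return A list of class `"window_set"`: `values` (matrix, one row per
#'   window), `starts` (0-based start indices), `labels` (majority label
#'   per window or `NULL`), `size`, `step`, `fs`.
#' @examples
#' w <- segment_windows(seq_len(28), size = 14, overlap = 0.5)
#' w$starts  # 0 7 14
#' @export
segment_windows <- function(series, size = 14, overlap = 0.5) {
  if (size < 2 || size != round(size)) stop("`size` must be an integer >= 2")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  x <- if (is.numeric(series)) series else series$value
  lab <- if (is.numeric(series)) NULL else series$label
  fs <- if (is.numeric(series)) NA_real_ else attr(series, "fs")
  step <- max(1L, as.integer(round(size * (1 - overlap))))
  n <- length(x)
  if (n < size)
    return(structure(list(values = matrix(numeric(0), 0, size),
                          starts = integer(0), labels = NULL,
                          size = as.integer(size), step = step, fs = fs),
                     class = "window_set"))
  starts <- seq.int(0L, n - size, by = step)
  vals <- t(vapply(starts, function(s) x[(s + 1L):(s + size)],
                   numeric(size)))
  labels <- NULL
  if (!is.null(lab)) {
    labels <- vapply(starts, function(s) {
      w <- lab[(s + 1L):(s + size)]
      w <- w[!is.na(w)]
      if (!length(w)) return(NA_character_)
      tab <- table(factor(w, levels = unique(w)))  # first-seen order
      names(tab)[which.max(tab)]                   # tie -> earlier label
    }, character(1))
  }
  structure(list(values = vals, starts = starts, labels = labels,
                 size = as.integer(size), step = step, fs = fs),
            class = "window_set")
}

#' Drop short behavior bouts
#'
#' Removes contiguous same-label runs shorter than `min_duration_s` from a
#' labeled resultant series before windowing; brief transitional snippets
#' carry too few samples to characterize a behavior. The retained runs are
#' concatenated, so windows are subsequently formed within the surviving
#' samples.
#'
#' @param series A labeled `resultant_series`.
#' @param min_duration_s Minimum bout duration in seconds (default 3).
#' @return The series with short bouts removed (possibly zero rows).
#' @export
exclude_short_bouts <- function(series, min_duration_s = 3.0) {
  stopifnot(inherits(series, "resultant_series"))
  if (is.null(series$label))
    stop("per-sample labels are required; for unlabeled streams skip bout ",
         "exclusion and call segment_windows() directly")
  if (nrow(series) == 0L) return(series)
  fs <- attr(series, "fs")
  min_samples <- min_duration_s * fs
  r <- rle(series$label)
  keep_run <- r$lengths >= min_samples
  keep <- rep(keep_run, r$lengths)
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, channel = attr(series, "channel"), fs = fs,
            class = class(series))
}

#' Write a resultant series to CSV
#'
#' @param series A `resultant_series`.
#' @param path Output path; columns `t,value[,label]`.
#' @export
write_resultant_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
}

#' Read a resultant series CSV written by [write_resultant_csv()]
#'
#' @param path CSV path with columns `t,value[,label]`.
#' @param channel Channel tag to attach.
#' @param fs Sampling rate; inferred from timestamps if `NULL`.
#' @export
read_resultant_csv <- function(path, channel = "acceleration", fs = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "value") %in% names(d)))
    stop("resultant CSV must have columns t,value[,label]")
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$t))
  new_resultant_series(d$t, d$value,
                       if ("label" %in% names(d)) d$label else NULL,
                       channel, fs)
}
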