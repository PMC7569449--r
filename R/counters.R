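#' Counter configuration
#'
#' Bundles the tunable parameters shared by the three counting methods.
#'
#' @param threshold_frac position of the crossing threshold within the signal
#'   range, in (0,1). Default 2/3: the threshold sits at two-thirds of the
#'   way from the minimum to the maximum of the series.
#' @param refractory_s refractory period in seconds (default 0.1): after a
#'   counted crossing, further upward crossings within this interval are
#'   suppressed so multi-peaked repetitions are not double counted.
#'   Suppressed crossings do not restart the period.
#' @param alpha coefficient of the first-order recursive low-pass filter,
#'   in (0,1); default 0.1 (i.e. `A[i] = 0.9 A[i-1] + 0.1 X[i]`).
#' @param band_hz two-element search band (Hz) for the dominant frequency,
#'   default `c(0.2, 5)`: plausible human repetition rates, excluding the DC
#'   bin and tremor-band noise.
#' @param round_mode how the Fourier count `f * T` becomes an integer:
#'   `"nearest"` (round half up, default) or `"floor"`.
#' @return An object of class `counter_config`.
#' @export
counter_config <- function(threshold_frac = 2 / 3, refractory_s = 0.1,
                           alpha = 0.1, band_hz = c(0.2, 5),
                           round_mode = c("nearest", "floor")) {
  round_mode <- match.arg(round_mode)
  if (!(is.numeric(threshold_frac) && length(threshold_frac) == 1 &&
        threshold_frac > 0 && threshold_frac < 1))
    stop("threshold_frac must lie in (0, 1)")
  if (!(is.numeric(refractory_s) && length(refractory_s) == 1 &&
        refractory_s >= 0))
    stop("refractory_s must be >= 0")
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)")
  if (!(is.numeric(band_hz) && length(band_hz) == 2 &&
        band_hz[1] >= 0 && band_hz[1] < band_hz[2]))
    stop("band_hz must be c(f_min, f_max) with 0 <= f_min < f_max")
  structure(list(threshold_frac = threshold_frac, refractory_s = refractory_s,
                 alpha = alpha, band_hz = band_hz, round_mode = round_mode),
            class = "counter_config")
}

.series_values <- function(series) {
  if (inherits(series, "signed_mag")) series$s
  else if (is.numeric(series)) as.numeric(series)
  else stop("series must be a signed_mag or a numeric vector")
}

.count_result <- function(method, count, duration_s,
                          threshold_used = NA_real_,
                          dominant_freq_hz = NA_real_) {
  structure(list(method = method, count = as.integer(count),
                 threshold_used = threshold_used,
                 dominant_freq_hz = dominant_freq_hz,
                 duration_s = duration_s),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("method: %s\ncount: %d\nduration_s: %.3f\n",
              x$method, x$count, x$duration_s))
  if (!is.na(x$threshold_used))
    cat(sprintf("threshold_used: %.4f m/s^2\n", x$threshold_used))
  if (!is.na(x$dominant_freq_hz))
    cat(sprintf("dominant_freq_hz: %.4f\n", x$dominant_freq_hz))
  invisible(x)
}

#' Crossing threshold for a series
#'
#' The threshold is placed a fixed fraction of the way through the signal
#' range: `tau = min(s) + frac * (max(s) - min(s))`. A degenerate series
#' (range below 1e-9) has no meaningful threshold and yields `NA`; the
#' counters translate that into a count of 0.
#'
#' @param series a `signed_mag` series or numeric vector.
#' @param threshold_frac fraction in (0,1), default 2/3.
#' @return The threshold in m/s^2, or `NA_real_` for a degenerate series.
#' @export
threshold_level <- function(series, threshold_frac = 2 / 3) {
  s <- .series_values(series)
  if (length(s) < 2) stop("series needs >= 2 samples")
  lo <- min(s); hi <- max(s)
  if (hi - lo < 1e-9) return(NA_real_)
  lo + threshold_frac * (hi - lo)
}

# indices k (>= 2) where s crosses tau upward: s[k-1] < tau <= s[k]
.upward_crossings <- function(s, tau) {
  n <- length(s)
  which(s[-n] < tau & s[-1] >= tau) + 1L
}

#' Count repetitions by threshold crossing
#'
#' One repetition is counted each time the signal crosses the threshold in
#' the positive direction (strictly below to at-or-above between consecutive
#' samples). After a counted crossing, crossings within the refractory
#' period are suppressed; suppressed crossings do not restart the period.
#'
#' @param series a `signed_mag` series (or numeric vector; then `fs` of 1 Hz
#'   is assumed and `refractory_s` is in samples).
#' @param config a [counter_config()].
#' @return A `count_result` with `method = "threshold"`.
#' @export
count_threshold <- function(series, config = counter_config()) {
  s <- .series_values(series)
  fs <- if (inherits(series, "signed_mag")) series$fs else 1
  duration <- (length(s) - 1) / fs
  tau <- threshold_level(series, config$threshold_frac)
  if (is.na(tau))
    return(.count_result("threshold", 0L, duration))
  cross_t <- (.upward_crossings(s, tau) - 1) / fs
  count <- 0L
  last <- -Inf
  for (tm in cross_t) {
    if (tm - last >= config$refractory_s) {
      count <- count + 1L
      last <- tm
    }
  }
  .count_result("threshold", count, duration, threshold_used = tau)
}

#' First-order recursive low-pass filter
#'
#' Exponentially weighted moving average
#' `A[i] = (1 - alpha) * A[i-1] + alpha * X[i]`, initialised at `A[1] = X[1]`
#' (no startup transient). With `init` supplied, the pre-signal state `A[0]`
#' is set to `init` instead, so `A[1] = (1 - alpha) * init + alpha * X[1]`;
#' feeding a unit impulse with `init = 0` exposes the closed-form impulse
#' response `alpha * (1 - alpha)^(n-1)`.
#'
#' @param series a `signed_mag` series or numeric vector.
#' @param alpha smoothing coefficient in (0,1); default 0.1.
#' @param init optional pre-signal filter state `A[0]`.
#' @return Filtered series of the same type and length as the input.
#' @export
lowpass_filter <- function(series, alpha = 0.1, init = NULL) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)")
  s <- .series_values(series)
  y0 <- if (is.null(init)) s[1] else as.numeric(init)
  y <- as.numeric(stats::filter(alpha * s, 1 - alpha,
                                method = "recursive", init = y0))
  if (inherits(series, "signed_mag"))
    as_signed_mag(y, fs = series$fs, t0 = series$t0, mode = series$mode)
  else y
}

#' Count repetitions by threshold crossing after low-pass filtering
#'
#' Identical to [count_threshold()] except the series is first smoothed with
#' [lowpass_filter()] and the threshold is recomputed on the filtered signal,
#' so narrow high-frequency noise peaks no longer trigger spurious counts.
#'
#' @inheritParams count_threshold
#' @return A `count_result` with `method = "threshold_lowpass"`.
#' @export
count_threshold_lowpass <- function(series, config = counter_config()) {
  filtered <- lowpass_filter(series, config$alpha)
  res <- count_threshold(filtered, config)
  res$method <- "threshold_lowpass"
  res
}

#' Count repetitions from the dominant Fourier frequency
#'
#' The mean is removed, the magnitude spectrum computed, and the dominant
#' frequency `f*` taken as the spectral argmax over bins inside the search
#' band (ties broken toward the lower frequency, which avoids locking onto a
#' harmonic). The count is `f* * T` with `T = (n-1)/fs` the series duration,
#' rounded per `config$round_mode`.
#'
#' @inheritParams count_threshold
#' @return A `count_result` with `method = "fourier"` and the dominant
#'   frequency in `dominant_freq_hz`.
#' @export
count_fourier <- function(series, config = counter_config()) {
  s <- .series_values(series)
  if (length(s) < 4) stop("series needs >= 4 samples for spectral counting")
  fs <- if (inherits(series, "signed_mag")) series$fs else 1
  n <- length(s)
  duration <- (n - 1) / fs
  spec <- Mod(stats::fft(s - mean(s)))
  k <- 1:(n %/% 2)              # positive-frequency bins, DC excluded
  freqs <- k * fs / n
  in_band <- freqs >= config$band_hz[1] & freqs <= config$band_hz[2]
  if (!any(in_band)) {
    warning("no spectral bin inside the search band; count set to 0")
    return(.count_result("fourier", 0L, duration))
  }
  fb <- freqs[in_band]
  mb <- spec[k + 1L][in_band]
  if (max(mb) <= 0)             # zero spectrum after mean removal
    return(.count_result("fourier", 0L, duration))
  f_star <- fb[which.max(mb)]   # first max = lowest frequency on ties
  raw <- f_star * duration
  count <- if (config$round_mode == "nearest") floor(raw + 0.5) else floor(raw)
  .count_result("fourier", count, duration, dominant_freq_hz = f_star)
}

#' Count repetitions in a trace or series
#'
#' User-facing front end: accepts a uniform 3-axis trace (preprocessed to a
#' signed magnitude first) or an already prepared `signed_mag` series, and
#' dispatches to the requested counting method(s).
#'
#' @param x a [uniform_trace()] or `signed_mag` series.
#' @param method one of `"threshold"`, `"threshold_lowpass"`, `"fourier"`,
#'   or `"all"` for a list of all three.
#' @param config a [counter_config()].
#' @param gravity_window_s,sign_mode preprocessing settings, used only when
#'   `x` is a trace (see [signed_magnitude()]).
#' @return A `count_result`, or a named list of them for `method = "all"`.
#' @examples
#' tt <- seq(0, 30, by = 1 / 50)
#' s <- as_signed_mag(sin(2 * pi * 0.5 * tt), fs = 50)
#' count_reps(s, "fourier")$count
#' @export
count_reps <- function(x, method = c("threshold", "threshold_lowpass",
                                     "fourier", "all"),
                       config = counter_config(),
                       gravity_window_s = 2, sign_mode = "dynamic") {
  method <- match.arg(method)
  series <- if (inherits(x, "uniform_trace"))
    preprocess_trace(x, gravity_window_s, sign_mode)
  else if (inherits(x, "signed_mag")) x
  else stop("x must be a uniform_trace or signed_mag")
  counters <- list(threshold = count_threshold,
                   threshold_lowpass = count_threshold_lowpass,
                   fourier = count_fourier)
  if (method == "all") lapply(counters, function(f) f(series, config))
  else counters[[method]](series, config)
}
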