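#' Per-sample acceleration magnitude
#'
#' Euclidean norm of the 3-axis acceleration vector at every sample.
#'
#' @param trace a [uniform_trace()].
#' @return Numeric vector of magnitudes in m/s^2 (all `>= 0`).
#' @export
compute_magnitude <- function(trace) {
  stopifnot(inherits(trace, "uniform_trace"))
  sqrt(trace$x^2 + trace$y^2 + trace$z^2)
}

# centered moving average with edge truncation (window shrinks near the ends
# so every output is a mean of available samples only); O(n) via cumsum
.moving_average <- function(v, w) {
  n <- length(v)
  if (w <= 1) return(v)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  idx <- seq_len(n)
  lo <- pmax(1L, idx - hl)
  hi <- pmin(n, idx + hr)
  cs <- c(0, cumsum(v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate the gravity baseline of a trace
#'
#' The slowly varying component of each axis, attributable to gravity plus
#' posture, estimated by a long-window centered moving average. The window is
#' truncated at the edges, so there is no phase lag and no padding artifact.
#'
#' @param trace a [uniform_trace()].
#' @param window_s averaging window in seconds (default 2 s: longer than the
#'   half-cycle of any plausible repetition, short enough to track slow
#'   orientation drift).
#' @return An object of class `gravity_estimate`: list with per-sample `gx`,
#'   `gy`, `gz` (m/s^2) and `window_s`.
#' @export
estimate_gravity <- function(trace, window_s = 2) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (length(window_s) != 1 || !is.finite(window_s) || window_s <= 0)
    stop("window_s must be > 0")
  w <- max(1L, as.integer(round(window_s * trace$fs)))
  structure(list(gx = .moving_average(trace$x, w),
                 gy = .moving_average(trace$y, w),
                 gz = .moving_average(trace$z, w),
                 window_s = window_s),
            class = "gravity_estimate")
}

#' Signed acceleration magnitude series
#'
#' Collapses a 3-axis trace to the scalar signal the repetition counters
#' consume. Taking a plain magnitude half-wave rectifies the oscillation
#' (negative excursions fold onto positive ones); the sign is therefore
#' restored from the gravity direction: samples whose motion component points
#' along gravity are positive, samples pointing against it are negative.
#'
#' With `mode = "dynamic"` (default) the gravity baseline `g_k` is first
#' subtracted and the signed norm of the dynamic residual `d_k = a_k - g_k`
#' is returned: `s_k = sign(d_k . ghat_k) * ||d_k||`. With `mode = "raw"` the
#' sign is applied to the raw magnitude instead: `s_k = sign(d_k . ghat_k) *
#' ||a_k||`. The raw magnitude is dominated by gravity and almost never
#' opposes it, so only the dynamic mode actually de-rectifies the signal;
#' `"raw"` is kept as an option. `sign(0)` is `+1`, and samples where the
#' gravity estimate has zero norm fall back to `+1`.
#'
#' @param trace a [uniform_trace()].
#' @param gravity a [estimate_gravity()] result; computed with
#'   `gravity_window_s` when `NULL`.
#' @param mode `"dynamic"` or `"raw"`.
#' @param gravity_window_s window used when `gravity` is `NULL`.
#' @return Object of class `signed_mag`: list with `s` (signed magnitude,
#'   m/s^2), `fs`, `t0` and `mode`.
#' @export
signed_magnitude <- function(trace, gravity = NULL,
                             mode = c("dynamic", "raw"),
                             gravity_window_s = 2) {
  stopifnot(inherits(trace, "uniform_trace"))
  mode <- match.arg(mode)
  if (is.null(gravity)) gravity <- estimate_gravity(trace, gravity_window_s)
  stopifnot(inherits(gravity, "gravity_estimate"))
  n <- length(trace$x)
  if (length(gravity$gx) != n) stop("gravity estimate length mismatch")
  dx <- trace$x - gravity$gx
  dy <- trace$y - gravity$gy
  dz <- trace$z - gravity$gz
  gn <- sqrt(gravity$gx^2 + gravity$gy^2 + gravity$gz^2)
  dot <- dx * gravity$gx + dy * gravity$gy + dz * gravity$gz
  sigma <- ifelse(gn > 0 & dot < 0, -1, 1)
  mag <- if (mode == "dynamic") sqrt(dx^2 + dy^2 + dz^2)
         else sqrt(trace$x^2 + trace$y^2 + trace$z^2)
  as_signed_mag(sigma * mag, fs = trace$fs, t0 = trace$t0, mode = mode)
}

#' Construct a signed-magnitude series directly
#'
#' Low-level constructor, mainly for simulated or externally prepared scalar
#' signals.
#'
#' @param s numeric signal values, m/s^2 (finite, length >= 2).
#' @param fs sampling rate in Hz.
#' @param t0 start time, seconds.
#' @param mode provenance tag, `"dynamic"` or `"raw"`.
#' @return A `signed_mag` object.
#' @export
as_signed_mag <- function(s, fs, t0 = 0, mode = "dynamic") {
  s <- as.numeric(s)
  if (length(s) < 2) stop("signed-magnitude series needs >= 2 samples")
  if (!all(is.finite(s))) stop("signed-magnitude series must be finite")
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0) stop("fs must be > 0")
  structure(list(s = s, fs = as.numeric(fs), t0 = as.numeric(t0),
                 mode = mode),
            class = "signed_mag")
}

#' Preprocess a uniform trace for counting
#'
#' Convenience wrapper: gravity estimation followed by [signed_magnitude()].
#'
#' @inheritParams signed_magnitude
#' @param sign_mode `"dynamic"` or `"raw"`.
#' @return A `signed_mag` series.
#' @export
preprocess_trace <- function(trace, gravity_window_s = 2,
                             sign_mode = c("dynamic", "raw")) {
  sign_mode <- match.arg(sign_mode)
  g <- estimate_gravity(trace, gravity_window_s)
  signed_magnitude(trace, g, mode = sign_mode)
}

#' @export
print.signed_mag <- function(x, ...) {
  cat(sprintf(
    "<signed_mag (%s): %d samples @ %g Hz, range [%.3f, %.3f] m/s^2>\n",
    x$mode, length(x$s), x$fs, min(x$s), max(x$s)))
  invisible(x)
}

#' @export
plot.signed_mag <- function(x, ...) {
  tt <- x$t0 + (seq_along(x$s) - 1) / x$fs
  graphics::plot(tt, x$s, type = "l", xlab = "time (s)",
                 ylab = expression(signed ~ magnitude ~ (m/s^2)), ...)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  invisible(x)
}
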