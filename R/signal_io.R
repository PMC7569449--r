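#' @title Accelerometer trace containers
#' @description
#' `accel_trace()` wraps a raw timestamped 3-axis recording; `uniform_trace()`
#' wraps the same channels on a uniform time grid. All acceleration is stored
#' internally in m/s^2; values recorded in g are converted with 1 g =
#' 9.80665 m/s^2 at construction time.
#'
#' @param t numeric vector of timestamps in seconds, non-decreasing.
#' @param x,y,z numeric acceleration channels, same length as `t`.
#' @param unit unit of the supplied values, `"ms2"` (m/s^2) or `"g"`.
#' @param source_id opaque label carried along for reporting.
#' @return An object of class `accel_trace`: a list with elements `t`, `x`,
#'   `y`, `z` (m/s^2), `unit_declared` and `source_id`.
#' @examples
#' tr <- accel_trace(c(0, 0.02), c(3, 3), c(4, 4), c(0, 0))
#' @export
accel_trace <- function(t, x, y, z, unit = c("ms2", "g"), source_id = "trace") {
  unit <- match.arg(unit)
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(t)
  if (!(length(x) == n && length(y) == n && length(z) == n))
    stop("t, x, y, z must have equal length")
  keep <- is.finite(t) & is.finite(x) & is.finite(y) & is.finite(z)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with non-finite values dropped")
    t <- t[keep]; x <- x[keep]; y <- y[keep]; z <- z[keep]
  }
  if (length(t) < 2) stop("accelerometer trace needs at least 2 valid samples")
  if (is.unsorted(t)) stop("timestamps must be non-decreasing")
  # duplicate timestamps: keep the first occurrence (deterministic, order-preserving)
  first <- !duplicated(t)
  t <- t[first]; x <- x[first]; y <- y[first]; z <- z[first]
  if (length(t) < 2) stop("fewer than 2 distinct timestamps")
  if (unit == "g") {
    x <- x * 9.80665; y <- y * 9.80665; z <- z * 9.80665
  }
  structure(list(t = t, x = x, y = y, z = z,
                 unit_declared = unit, source_id = source_id),
            class = "accel_trace")
}

#' @rdname accel_trace
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time of the grid, seconds.
#' @export
uniform_trace <- function(x, y, z, fs, t0 = 0) {
  fs <- as.numeric(fs)
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0) stop("fs must be a positive number")
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 2) stop("uniform trace needs at least 2 samples")
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 fs = fs, t0 = as.numeric(t0)),
            class = "uniform_trace")
}

#' Time stamps of a uniform trace
#'
#' @param trace a `uniform_trace`.
#' @return Numeric vector `t0 + k/fs`, `k = 0 .. n-1`.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "uniform_trace"))
  trace$t0 + (seq_along(trace$x) - 1) / trace$fs
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace '%s': %d samples, %.2f-%.2f s, unit %s>\n",
              x$source_id, length(x$t), x$t[1], x$t[length(x$t)],
              x$unit_declared))
  invisible(x)
}

#' @export
print.uniform_trace <- function(x, ...) {
  cat(sprintf("<uniform_trace: %d samples @ %g Hz, t0 = %g s, %.2f s span>\n",
              length(x$x), x$fs, x$t0, (length(x$x) - 1) / x$fs))
  invisible(x)
}

#' Read a delimited accelerometer trace
#'
#' Reads a comma- or tab-delimited text file whose first four numeric columns
#' are time, x, y, z. The delimiter and an optional header row are
#' auto-detected (a header is assumed when the first row is not fully
#' numeric). Rows containing non-finite values are dropped with a warning;
#' duplicate timestamps keep the first occurrence.
#'
#' @param path file path.
#' @param unit acceleration unit in the file: `"ms2"` or `"g"` (converted to
#'   m/s^2 on load).
#' @param time_unit `"s"` (default) or `"ms"`; millisecond timestamps are
#'   divided by 1000.
#' @return An [accel_trace()].
#' @export
read_trace <- function(path, unit = c("ms2", "g"), time_unit = c("s", "ms")) {
  unit <- match.arg(unit)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("malformed trace file (empty): ", path)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else
         if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  toks <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(toks))))
  dat <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 4) stop("malformed trace file (need >= 4 columns): ", path)
  if (nrow(dat) < 2) stop("malformed trace file (< 2 rows): ", path)
  dat <- dat[, 1:4]
  num <- vapply(dat, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(dat)))
  t <- num[, 1]
  if (time_unit == "ms") t <- t / 1000
  tr <- tryCatch(
    accel_trace(t, num[, 2], num[, 3], num[, 4], unit = unit,
                source_id = basename(path)),
    error = function(e) stop("malformed trace file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  tr
}

#' Write a trace as delimited text
#'
#' Writes columns `t,x,y,z` (comma-separated, header row, values in m/s^2)
#' with a fixed 6-decimal representation, the same layout [read_trace()]
#' accepts.
#'
#' @param trace an `accel_trace` or `uniform_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "uniform_trace")) {
    t <- trace_times(trace)
  } else if (inherits(trace, "accel_trace")) {
    t <- trace$t
  } else stop("trace must be an accel_trace or uniform_trace")
  fmt <- function(v) sprintf("%.6f", v)
  lines <- c("t,x,y,z",
             paste(fmt(t), fmt(trace$x), fmt(trace$y), fmt(trace$z), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a trace onto a uniform grid
#'
#' Linearly interpolates each axis onto the grid `t0 + k/fs`,
#' `k = 0 .. floor((t_end - t0) * fs)`. No extrapolation: the grid never
#' extends beyond the recorded time span.
#'
#' @param trace an [accel_trace()].
#' @param fs target sampling rate in Hz (default 50, typical of phone
#'   accelerometers and well above any plausible repetition frequency).
#' @return A [uniform_trace()].
#' @export
resample_uniform <- function(trace, fs = 50) {
  stopifnot(inherits(trace, "accel_trace"))
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0) stop("fs must be > 0")
  t0 <- trace$t[1]
  t_end <- trace$t[length(trace$t)]
  if (t_end - t0 < 2 / fs) stop("trace too short to resample at ", fs, " Hz")
  nk <- floor((t_end - t0) * fs + 1e-9)
  grid <- t0 + (0:nk) / fs
  interp <- function(v) stats::approx(trace$t, v, xout = grid,
                                      method = "linear", rule = 1)$y
  uniform_trace(interp(trace$x), interp(trace$y), interp(trace$z),
                fs = fs, t0 = t0)
}

#' Trim a uniform trace to a closed time interval
#'
#' Keeps samples whose time lies in `[t_start, t_end]`; the sampling rate is
#' unchanged. Used to cut non-exercise data at the beginning and end of a
#' recorded bout.
#'
#' @param trace a [uniform_trace()].
#' @param t_start,t_end interval bounds in seconds,
#'   `t0 <= t_start < t_end <=` trace end.
#' @return A [uniform_trace()].
#' @export
trim <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "uniform_trace"))
  tt <- trace_times(trace)
  eps <- 1e-9 * max(1, abs(t_end))
  if (t_start >= t_end) stop("empty trim interval: t_start must be < t_end")
  if (t_start < trace$t0 - eps || t_end > tt[length(tt)] + eps)
    stop("trim interval outside trace span")
  keep <- tt >= t_start - eps & tt <= t_end + eps
  if (sum(keep) < 2) stop("trim interval contains fewer than 2 samples")
  uniform_trace(trace$x[keep], trace$y[keep], trace$z[keep],
                fs = trace$fs, t0 = tt[keep][1])
}

#' @export
plot.uniform_trace <- function(x, ...) {
  tt <- trace_times(x)
  rng <- range(x$x, x$y, x$z)
  graphics::plot(tt, x$x, type = "l", col = "firebrick", ylim = rng,
                 xlab = "time (s)", ylab = expression(acceleration ~ (m/s^2)),
                 ...)
  graphics::lines(tt, x$y, col = "forestgreen")
  graphics::lines(tt, x$z, col = "steelblue")
  graphics::legend("topright", c("x", "y", "z"), lty = 1, bty = "n",
                   col = c("firebrick", "forestgreen", "steelblue"))
  invisible(x)
}
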