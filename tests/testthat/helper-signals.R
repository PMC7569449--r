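# shared fixtures: all built in code at test time

# sampled sinusoid as a signed-magnitude series
make_sine <- function(f, duration_s = 30, fs = 50, amp = 1, phase = 0) {
  tt <- seq(0, duration_s, by = 1 / fs)
  as_signed_mag(amp * sin(2 * pi * f * tt + phase), fs = fs)
}

# literal reference counter: scans every sample pair and applies the
# threshold + refractory rules one step at a time (independent of the
# vectorised implementation)
oracle_count_threshold <- function(s, fs, threshold_frac = 2 / 3,
                                   refractory_s = 0.1) {
  lo <- min(s); hi <- max(s)
  if (hi - lo < 1e-9) return(0L)
  tau <- lo + threshold_frac * (hi - lo)
  count <- 0L
  last <- -Inf
  for (k in 2:length(s)) {
    if (s[k - 1] < tau && s[k] >= tau) {
      tm <- (k - 1) / fs
      if (tm - last >= refractory_s) {
        count <- count + 1L
        last <- tm
      }
    }
  }
  count
}

# write a small delimited trace file, returning its path
write_temp_trace <- function(rows, sep = ",", header = NULL) {
  path <- tempfile(fileext = ".csv")
  lines <- apply(rows, 1, paste, collapse = sep)
  if (!is.null(header)) lines <- c(paste(header, collapse = sep), lines)
  writeLines(lines, path)
  path
}

# double-peak test signal: unit pulses at t = offset + k*spacing_pair_s and
# pair_gap_s later, on a zero baseline
make_pulse_pairs <- function(pair_gap_s, duration_s = 10, fs = 100,
                             spacing_s = 2, offset_s = 0.5) {
  n <- duration_s * fs + 1
  s <- numeric(n)
  starts <- seq(offset_s, duration_s - spacing_s / 2, by = spacing_s)
  for (t0 in starts) {
    s[round(t0 * fs) + 1] <- 1
    s[round((t0 + pair_gap_s) * fs) + 1] <- 1
  }
  as_signed_mag(s, fs = fs)
}
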