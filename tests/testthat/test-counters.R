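test_that("threshold_level sits at the configured fraction of the range", {
  expect_equal(threshold_level(c(0, 3, 1), 2 / 3), 2)
  expect_equal(threshold_level(c(-1, 1, 0), 2 / 3), 1 / 3)
  expect_true(is.na(threshold_level(rep(5, 10))))
})

test_that("count_threshold counts one upward crossing per period", {
  s <- make_sine(1, duration_s = 10, fs = 100)
  expect_equal(count_threshold(s)$count,
               oracle_count_threshold(s$s, 100))
  expect_equal(count_threshold(s)$count, 10L)
  expect_equal(count_threshold(s)$duration_s, 10)
  # constant series: degenerate, count 0
  r <- count_threshold(as_signed_mag(rep(2, 100), fs = 50))
  expect_equal(r$count, 0L)
  expect_true(is.na(r$threshold_used))
})

test_that("refractory period suppresses the second peak of close pairs", {
  # peaks 0.05 s apart, one pair every 2 s over 10 s
  close_pairs <- make_pulse_pairs(0.05)
  expect_equal(count_threshold(close_pairs)$count, 5L)
  # widening the pair beyond the refractory period counts both peaks
  wide_pairs <- make_pulse_pairs(0.15)
  expect_equal(count_threshold(wide_pairs)$count, 10L)
  # suppressed crossings must not restart the refractory clock: three
  # pulses 0.06 s apart -> first and third counted
  fs <- 100
  s <- numeric(201)
  s[c(51, 57, 63)] <- 1
  expect_equal(count_threshold(as_signed_mag(s, fs = fs))$count, 2L)
})

test_that("increasing the refractory period never increases the count", {
  set.seed(101)
  for (rep_i in 1:20) {
    s <- as_signed_mag(cumsum(rnorm(300)), fs = 50)
    counts <- vapply(c(0, 0.05, 0.1, 0.2), function(r)
      count_threshold(s, counter_config(refractory_s = r))$count, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("lowpass_filter implements the first-order recursion", {
  # one step by hand: A1 = X1, A2 = 0.9*10 + 0.1*0
  expect_equal(lowpass_filter(c(10, 0), 0.1), c(10, 9))
  # a constant is a fixed point
  expect_equal(lowpass_filter(rep(3.7, 20), 0.1), rep(3.7, 20))
  # impulse with zeroed initial state exposes alpha*(1-alpha)^(n-1)
  imp <- lowpass_filter(c(1, 0, 0, 0), 0.1, init = 0)
  expect_equal(imp, c(0.1, 0.09, 0.081, 0.0729))
  expect_error(lowpass_filter(c(1, 2), alpha = 1), "alpha")
  expect_error(lowpass_filter(c(1, 2), alpha = 0), "alpha")
})

test_that("lowpass_filter output stays inside the input range", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(200) + ifelse(i %% 2, cumsum(rnorm(200, 0, 0.3)), 0)
    y <- lowpass_filter(x, alpha = runif(1, 0.05, 0.95))
    expect_gte(min(y), min(x) - 1e-12)
    expect_lte(max(y), max(x) + 1e-12)
  }
})

test_that("count_threshold_lowpass equals counting the filtered series", {
  set.seed(31)
  s <- as_signed_mag(sin(seq(0, 60, by = 0.02)) + rnorm(3001, 0, 0.3),
                     fs = 50)
  cfg <- counter_config()
  direct <- count_threshold_lowpass(s, cfg)
  composed <- count_threshold(lowpass_filter(s, cfg$alpha), cfg)
  expect_identical(direct$count, composed$count)
  expect_identical(direct$threshold_used, composed$threshold_used)
  expect_equal(direct$method, "threshold_lowpass")
})

test_that("low-pass filtering removes spike-induced overcount", {
  fs <- 50
  s <- make_sine(1, duration_s = 30, fs = fs)
  # single-sample downward spikes of 3x amplitude near each peak create a
  # second upward crossing per period in the raw signal
  spike_at <- round((seq(0.26, 29.26, by = 1)) * fs) + 1
  x <- s$s
  x[spike_at] <- x[spike_at] - 3
  spiky <- as_signed_mag(x, fs = fs)
  raw <- count_threshold(spiky)$count
  filt <- count_threshold_lowpass(spiky)$count
  expect_gt(raw, 30)
  expect_equal(filt, 30L)
  # both paths agree with the literal reference counter
  expect_equal(raw, oracle_count_threshold(spiky$s, fs))
  expect_equal(filt,
               oracle_count_threshold(lowpass_filter(spiky, 0.1)$s, fs))
  # and the clean sinusoid still counts once per period after filtering
  expect_equal(count_threshold_lowpass(s)$count, 30L)
})

test_that("count_fourier counts dominant frequency times duration", {
  r <- count_fourier(make_sine(0.5, 30, 50))
  expect_equal(r$count, 15L)
  expect_equal(r$dominant_freq_hz, 0.5, tolerance = 0.02)
  expect_equal(r$count, round(r$dominant_freq_hz * r$duration_s))

  # stronger low component wins over a weak fast one
  tt <- seq(0, 20, by = 1 / 50)
  s <- as_signed_mag(2 * sin(2 * pi * 0.5 * tt) + 0.5 * sin(2 * pi * 3 * tt),
                     fs = 50)
  expect_equal(count_fourier(s)$count, 10L)

  # constant series: nothing in band after mean removal
  r <- count_fourier(as_signed_mag(rep(1, 100), fs = 50))
  expect_equal(r$count, 0L)

  # empty search band warns and returns 0
  s <- make_sine(1, 10, 50)
  expect_warning(
    r <- count_fourier(s, counter_config(band_hz = c(30, 40))),
    "band")
  expect_equal(r$count, 0L)

  # floor rounding mode
  s <- make_sine(0.52, 10, 50)
  rn <- count_fourier(s, counter_config(round_mode = "nearest"))
  rf <- count_fourier(s, counter_config(round_mode = "floor"))
  expect_lte(rf$count, rn$count)
})

test_that("counts are invariant to positive rescaling of the signal", {
  set.seed(47)
  s0 <- sin(seq(0, 40, by = 0.02)) + rnorm(2001, 0, 0.2)
  for (c_scale in c(0.5, 2, 17)) {
    a <- as_signed_mag(s0, fs = 50)
    b <- as_signed_mag(c_scale * s0, fs = 50)
    expect_identical(count_threshold(a)$count, count_threshold(b)$count)
    expect_identical(count_threshold_lowpass(a)$count,
                     count_threshold_lowpass(b)$count)
    expect_identical(count_fourier(a)$count, count_fourier(b)$count)
  }
})

test_that("count_reps dispatches on trace or series and validates method", {
  s <- make_sine(0.5, 30, 50)
  all3 <- count_reps(s, "all")
  expect_named(all3, c("threshold", "threshold_lowpass", "fourier"))
  expect_equal(count_reps(s, "fourier")$count, 15L)
  expect_error(count_reps(1:10, "fourier"), "uniform_trace or signed_mag")
})

test_that("counter_config validates its parameters", {
  expect_error(counter_config(threshold_frac = 0), "threshold_frac")
  expect_error(counter_config(threshold_frac = 1), "threshold_frac")
  expect_error(counter_config(refractory_s = -0.1), "refractory_s")
  expect_error(counter_config(alpha = 1.5), "alpha")
  expect_error(counter_config(band_hz = c(5, 0.2)), "band_hz")
})
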