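test_that("rmse computes the root-mean-square count error", {
  expect_equal(rmse(c(10, 12), c(10, 10)), sqrt(2))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(7, 4), 3)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("rmse detects constant offsets and ignores pairing order", {
  set.seed(9)
  x <- rpois(20, 15)
  expect_equal(rmse(x + 4, x), 4)
  expect_equal(rmse(x - 2, x), 2)
  perm <- sample(20)
  expect_equal(rmse(x[perm] + 3, x[perm]), rmse(x + 3, x))
})

# two noiseless sessions whose counters are exact, with truths offset to
# produce known per-exercise errors
.offset_sessions <- function(errors) {
  sp <- archetype_spec("demo", 1, 5)
  lapply(seq_along(errors), function(i) {
    s <- generate_session(sp, 30, 50, seed = i)
    s$archetype <- paste0("ex", i)
    s$true_count <- s$true_count - errors[i]
    s
  })
}

test_that("evaluate_sessions scores perfect counters as zero RMSE", {
  sp <- archetype_spec("easy", 1, 5)
  sessions <- lapply(1:3, function(i) generate_session(sp, 30, 50, seed = i))
  rep <- evaluate_sessions(sessions)
  expect_true(all(rep$per_cell == 0))
  expect_true(all(rep$per_method_avg == 0))
  expect_equal(unname(rep$n_sessions["easy"]), 3)
})

test_that("pooled average differs from mean of per-exercise RMSEs", {
  # squared errors 9 and 16 in two one-session exercises:
  # pooled sqrt(12.5), mean of cells 3.5
  sessions <- .offset_sessions(c(3, 4))
  rep <- evaluate_sessions(sessions, methods = "fourier")
  expect_equal(unname(rep$per_cell[, "fourier"]), c(3, 4))
  expect_equal(unname(rep$per_method_avg["fourier"]), sqrt(12.5))
  expect_equal(unname(rep$per_method_mean_cells["fourier"]), 3.5)
})

test_that("evaluate_sessions validates inputs and method names", {
  sessions <- .offset_sessions(c(0))
  expect_error(evaluate_sessions(list()), "no sessions")
  expect_error(evaluate_sessions(sessions, methods = "wavelet"), "methods")
  bad <- sessions
  bad[[1]]$true_count <- NULL
  expect_error(evaluate_sessions(bad), "true_count")
})

test_that("report printing and writing include both average rows", {
  sessions <- .offset_sessions(c(3, 4))
  rep <- evaluate_sessions(sessions)
  out <- capture.output(print(rep))
  expect_true(any(grepl("Avg \\(pooled\\)", out)))
  p <- tempfile(fileext = ".tsv")
  write_report(rep, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), 4)  # 2 exercises + 2 average rows
  expect_true(all(c("threshold", "fourier") %in% names(tab)))
})

test_that("tune_threshold minimises pooled RMSE with smallest-frac ties", {
  sp <- archetype_spec("easy", 1, 5)
  sessions <- lapply(1:2, function(i) generate_session(sp, 30, 50, seed = i))
  # single candidate
  expect_equal(tune_threshold(sessions, grid = 0.5)$best_frac, 0.5)
  # noiseless sinusoid-like sessions: every fraction is perfect, the
  # tie-break picks the smallest grid value
  tuned <- tune_threshold(sessions, grid = c(0.7, 0.3, 0.5))
  expect_equal(tuned$best_frac, 0.3)
  expect_equal(tuned$best_rmse, 0)
  expect_true(all(tuned$table$rmse == 0))
  # returned optimum is internally consistent with the table
  noisy <- generate_benchmark(default_archetypes()["upper_trunk_rotation"],
                              n_subjects = 4, seed = 11)
  tuned <- tune_threshold(noisy, grid = seq(0.2, 0.8, by = 0.2))
  expect_equal(tuned$best_rmse, min(tuned$table$rmse))
  expect_equal(tuned$table$rmse[tuned$table$frac == tuned$best_frac],
               tuned$best_rmse)
  expect_error(tune_threshold(sessions, grid = numeric(0)), "grid")
  expect_error(tune_threshold(sessions, grid = c(0.5, 1.2)), "grid")
})

test_that("a discriminating grid prefers the lower-error fraction", {
  # crafted waveform: main peak each period plus a secondary bump at 55%
  # of the range; a low threshold double-counts, a high one does not
  fs <- 50
  tt <- seq(0, 29.98, by = 1 / fs)
  ph <- (tt %% 2) / 2
  x <- 3 * (exp(-((ph - 0.25) / 0.06)^2) + 0.55 * exp(-((ph - 0.7) / 0.06)^2))
  s <- as_signed_mag(x, fs = fs)
  low <- count_threshold(s, counter_config(threshold_frac = 0.3))$count
  high <- count_threshold(s, counter_config(threshold_frac = 0.8))$count
  expect_equal(low, 30L)   # both bumps cross
  expect_equal(high, 15L)  # only the main peak crosses

  # the same waveform embedded in a gravity-bearing trace: the tuner picks
  # the fraction whose counts match the 15 true repetitions
  n <- length(tt)
  trace <- uniform_trace(rep(0, n), rep(0, n), 9.80665 + x, fs = fs)
  sessions <- list(structure(
    list(trace = trace, archetype = "crafted", true_count = 15),
    class = "session_record"))
  tuned <- tune_threshold(sessions, grid = c(0.3, 0.8))
  expect_equal(tuned$best_frac, 0.8)
})
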