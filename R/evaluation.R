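#' Root-mean-square error of counts
#'
#' @param estimates numeric vector of estimated counts.
#' @param truths numeric vector of true counts, same length.
#' @return `sqrt(mean((estimates - truths)^2))`.
#' @examples
#' rmse(c(10, 12), c(10, 10))  # sqrt(2)
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) == 0 || length(estimates) != length(truths))
    stop("estimates and truths must be non-empty and of equal length")
  sqrt(mean((as.numeric(estimates) - as.numeric(truths))^2))
}

.all_methods <- c("threshold", "threshold_lowpass", "fourier")

# counts for one prepared series under one method
.count_one <- function(series, method, config) {
  switch(method,
         threshold = count_threshold(series, config),
         threshold_lowpass = count_threshold_lowpass(series, config),
         fourier = count_fourier(series, config),
         stop("unknown method: ", method))$count
}

# preprocess every session once; returns list(series=..., keep=logical)
.prepare_sessions <- function(sessions, gravity_window_s, sign_mode) {
  series <- vector("list", length(sessions))
  keep <- logical(length(sessions))
  for (i in seq_along(sessions)) {
    series[[i]] <- tryCatch(
      preprocess_trace(sessions[[i]]$trace, gravity_window_s, sign_mode),
      error = function(e) {
        warning("session ", i, " (", sessions[[i]]$archetype,
                ") excluded: ", conditionMessage(e))
        NULL
      })
    keep[i] <- !is.null(series[[i]])
  }
  list(series = series, keep = keep)
}

#' Evaluate counting methods against ground truth
#'
#' Runs preprocessing and each counting method on every session and scores
#' the estimated against the true repetition counts. RMSE is reported per
#' (exercise, method) cell; the per-method average is the pooled RMSE over
#' all sessions (square root of the mean squared error across every session
#' of that method), with the mean of the per-exercise RMSEs reported
#' alongside since the two aggregations differ.
#'
#' @param sessions list of `session_record`s (see [generate_session()]), each
#'   with a `true_count`.
#' @param methods character subset of
#'   `c("threshold", "threshold_lowpass", "fourier")`.
#' @param config a [counter_config()].
#' @param gravity_window_s,sign_mode preprocessing settings
#'   (see [signed_magnitude()]).
#' @return Object of class `rep_eval`: list with `per_cell` (exercise x
#'   method RMSE matrix), `per_method_avg` (pooled), `per_method_mean_cells`,
#'   `n_sessions` per exercise, and `counts` (long data frame of every
#'   estimate).
#' @export
evaluate_sessions <- function(sessions, methods = .all_methods,
                              config = counter_config(),
                              gravity_window_s = 2, sign_mode = "dynamic") {
  if (length(sessions) == 0) stop("no sessions supplied")
  if (length(methods) == 0 || !all(methods %in% .all_methods))
    stop("methods must be a non-empty subset of: ",
         paste(.all_methods, collapse = ", "))
  truths <- vapply(sessions, function(s) {
    if (is.null(s$true_count)) stop("session without true_count")
    as.numeric(s$true_count)
  }, numeric(1))
  prep <- .prepare_sessions(sessions, gravity_window_s, sign_mode)
  if (!any(prep$keep)) stop("all sessions failed preprocessing")
  use <- which(prep$keep)
  exercises <- vapply(sessions, `[[`, "", "archetype")

  counts <- do.call(rbind, lapply(use, function(i) {
    data.frame(session = i, exercise = exercises[i],
               method = methods,
               estimate = vapply(methods, function(m)
                 .count_one(prep$series[[i]], m, config), numeric(1)),
               truth = truths[i], row.names = NULL)
  }))

  ex_levels <- unique(exercises[use])
  per_cell <- matrix(NA_real_, nrow = length(ex_levels),
                     ncol = length(methods),
                     dimnames = list(ex_levels, methods))
  for (ex in ex_levels) for (m in methods) {
    sub <- counts[counts$exercise == ex & counts$method == m, ]
    per_cell[ex, m] <- rmse(sub$estimate, sub$truth)
  }
  per_method_avg <- vapply(methods, function(m) {
    sub <- counts[counts$method == m, ]
    rmse(sub$estimate, sub$truth)
  }, numeric(1))
  per_method_mean_cells <- colMeans(per_cell)
  n_sessions <- vapply(ex_levels, function(ex)
    sum(exercises[use] == ex), numeric(1))

  structure(list(per_cell = per_cell, per_method_avg = per_method_avg,
                 per_method_mean_cells = per_method_mean_cells,
                 n_sessions = n_sessions, counts = counts,
                 methods = methods),
            class = "rep_eval")
}

#' @export
print.rep_eval <- function(x, digits = 2, ...) {
  cat("RMSE of repetition counts\n\n")
  tab <- rbind(x$per_cell,
               `Avg (pooled)` = x$per_method_avg,
               `Avg (mean of rows)` = x$per_method_mean_cells)
  print(round(tab, digits))
  cat("\nsessions per exercise:",
      paste(names(x$n_sessions), x$n_sessions, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the per-exercise x per-method RMSE table (with both average rows)
#' as tab-delimited text.
#'
#' @param report a `rep_eval` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "rep_eval"))
  tab <- rbind(report$per_cell,
               `Avg (pooled)` = report$per_method_avg,
               `Avg (mean of rows)` = report$per_method_mean_cells)
  df <- data.frame(exercise = rownames(tab), round(tab, 4),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tune the threshold fraction by grid search
#'
#' Evaluates one threshold-based counting method at every candidate fraction
#' and returns the fraction minimising the pooled RMSE over the supplied
#' sessions (ties broken toward the smaller fraction). Sessions are
#' preprocessed (and, for the low-pass method, filtered) once, so the grid
#' sweep is cheap.
#'
#' @param sessions list of `session_record`s with true counts.
#' @param grid candidate fractions in (0,1); default `seq(0.05, 0.95, 0.05)`.
#' @param method `"threshold"` or `"threshold_lowpass"`.
#' @param config a [counter_config()]; its `threshold_frac` is overridden by
#'   each grid value in turn.
#' @param gravity_window_s,sign_mode preprocessing settings.
#' @return Object of class `rep_tune`: list with `best_frac`, `best_rmse`
#'   and the per-fraction `table`.
#' @export
tune_threshold <- function(sessions, grid = seq(0.05, 0.95, by = 0.05),
                           method = c("threshold", "threshold_lowpass"),
                           config = counter_config(),
                           gravity_window_s = 2, sign_mode = "dynamic") {
  method <- match.arg(method)
  if (length(grid) == 0) stop("grid must be non-empty")
  if (any(grid <= 0 | grid >= 1)) stop("grid fractions must lie in (0, 1)")
  grid <- sort(grid)
  truths <- vapply(sessions, function(s) as.numeric(s$true_count), numeric(1))
  prep <- .prepare_sessions(sessions, gravity_window_s, sign_mode)
  if (!any(prep$keep)) stop("all sessions failed preprocessing")
  use <- which(prep$keep)
  series <- prep$series[use]
  if (method == "threshold_lowpass")
    series <- lapply(series, lowpass_filter, alpha = config$alpha)
  scores <- vapply(grid, function(fr) {
    cfg <- config
    cfg$threshold_frac <- fr
    est <- vapply(series, function(s) count_threshold(s, cfg)$count,
                  numeric(1))
    rmse(est, truths[use])
  }, numeric(1))
  best <- which.min(scores)   # grid sorted ascending: ties -> smaller frac
  structure(list(best_frac = grid[best], best_rmse = scores[best],
                 method = method,
                 table = data.frame(frac = grid, rmse = scores)),
            class = "rep_tune")
}

#' @export
print.rep_tune <- function(x, ...) {
  cat(sprintf("threshold tuning (%s): best frac %.3f, pooled RMSE %.3f\n",
              x$method, x$best_frac, x$best_rmse))
  invisible(x)
}
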