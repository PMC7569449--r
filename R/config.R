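.rc_defaults <- function() {
  list(fs = 50, unit = "ms2", time_unit = "s",
       gravity_window_s = 2, sign_mode = "dynamic",
       threshold_frac = 2 / 3, refractory_s = 0.1, alpha = 0.1,
       band_hz = c(0.2, 5), round_mode = "nearest",
       duration_s = 30, n_subjects = 18, seed = 1)
}

#' Run configuration
#'
#' Collects every tunable setting of the pipeline (I/O conventions,
#' preprocessing, counter parameters, generator sizes, seed) with defaults.
#' Unknown keys are rejected by name, so typos in config files fail loudly.
#'
#' @param ... named overrides of the defaults, or a single named list.
#' @return Named list of class `run_config`.
#' @examples
#' run_config(threshold_frac = 0.5, seed = 7)
#' @export
run_config <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.list(dots[[1]]))
    dots <- dots[[1]]
  cfg <- .rc_defaults()
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all config entries must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  # validate by constructing the counter config and checking the rest
  as_counter_config(cfg)
  if (!cfg$sign_mode %in% c("dynamic", "raw"))
    stop("sign_mode must be 'dynamic' or 'raw'")
  if (!cfg$unit %in% c("ms2", "g")) stop("unit must be 'ms2' or 'g'")
  if (!cfg$time_unit %in% c("s", "ms")) stop("time_unit must be 's' or 'ms'")
  if (!(cfg$fs > 0)) stop("fs must be > 0")
  if (!(cfg$gravity_window_s > 0)) stop("gravity_window_s must be > 0")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with a flat mapping of [run_config()] keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  run_config(yaml::read_yaml(path))
}

#' Extract the counter settings from a run configuration
#'
#' @param config a `run_config` (or plain named list with the counter keys).
#' @return A [counter_config()].
#' @export
as_counter_config <- function(config) {
  counter_config(threshold_frac = config$threshold_frac,
                 refractory_s = config$refractory_s,
                 alpha = config$alpha,
                 band_hz = as.numeric(config$band_hz),
                 round_mode = config$round_mode)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k,
                                  paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}
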