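#' Exercise archetype specification
#'
#' Parameter set describing one class of repetitive exercise for the
#' synthetic session generator: a fundamental repetition frequency, the peak
#' dynamic acceleration, relative harmonic content (motions are periodic but
#' not sinusoidal), cycle-to-cycle period and amplitude jitter, additive
#' sensor/motion noise, and the device orientation relative to gravity with
#' an optional slow drift. These parameters are the package's own
#' calibration of plausible exercise signals, not measured values.
#'
#' @param name label, e.g. `"arm_circle"`.
#' @param rep_freq_hz fundamental repetition frequency, Hz (> 0).
#' @param amplitude_ms2 peak dynamic acceleration of the fundamental, m/s^2.
#' @param harmonic_weights relative amplitudes of harmonics `2..K`
#'   (fundamental has weight 1); may be empty.
#' @param freq_jitter_cv coefficient of variation of the per-repetition
#'   period (lognormal, >= 0).
#' @param amp_jitter_cv coefficient of variation of the per-repetition
#'   amplitude (Gaussian truncated at 3 SD, >= 0).
#' @param noise_sd_ms2 white Gaussian noise SD added per axis, m/s^2.
#' @param orientation unit 3-vector: device axis along which gravity acts at
#'   the start of the session.
#' @param drift_deg_per_s slow rotation of the orientation, degrees/second.
#' @return Object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, rep_freq_hz, amplitude_ms2,
                           harmonic_weights = numeric(0),
                           freq_jitter_cv = 0, amp_jitter_cv = 0,
                           noise_sd_ms2 = 0, orientation = c(0, 0, 1),
                           drift_deg_per_s = 0) {
  if (!(rep_freq_hz > 0)) stop("rep_freq_hz must be > 0")
  if (!(amplitude_ms2 > 0)) stop("amplitude_ms2 must be > 0")
  if (freq_jitter_cv < 0 || amp_jitter_cv < 0) stop("jitter CVs must be >= 0")
  if (noise_sd_ms2 < 0) stop("noise_sd_ms2 must be >= 0")
  if (length(orientation) != 3 || any(!is.finite(orientation)))
    stop("orientation must be a finite 3-vector")
  nrm <- sqrt(sum(orientation^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm == 0) stop("orientation must be non-zero")
    orientation <- orientation / nrm
  }
  if (any(harmonic_weights < 0)) stop("harmonic_weights must be >= 0")
  structure(list(name = name, rep_freq_hz = rep_freq_hz,
                 amplitude_ms2 = amplitude_ms2,
                 harmonic_weights = as.numeric(harmonic_weights),
                 freq_jitter_cv = freq_jitter_cv,
                 amp_jitter_cv = amp_jitter_cv,
                 noise_sd_ms2 = noise_sd_ms2,
                 orientation = orientation,
                 drift_deg_per_s = drift_deg_per_s),
            class = "archetype_spec")
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf(
    "<archetype '%s': %.2f Hz, amp %.1f m/s^2, noise sd %.2f, jitter cv %.2f/%.2f>\n",
    x$name, x$rep_freq_hz, x$amplitude_ms2, x$noise_sd_ms2,
    x$freq_jitter_cv, x$amp_jitter_cv))
  invisible(x)
}

#' Built-in exercise archetypes
#'
#' Ten presets graded from large, highly periodic motions (arm circles,
#' squats, push-ups — big amplitude, little jitter, little noise) to small,
#' irregular ones (bridge, upper trunk rotation — small amplitude, strong
#' jitter and noise). The grading makes the hard archetypes genuinely harder
#' for every counting method, mirroring the easy/hard contrast seen in real
#' exercise recordings.
#'
#' @return Named list of ten [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  up <- c(0, 0, 1)
  tilt <- c(0, 1, 1) / sqrt(2)
  side <- c(1, 0, 1) / sqrt(2)
  specs <- list(
    archetype_spec("arm_circle", 1.00, 8.0, c(0.20),
                   0.02, 0.05, 0.30, up, 0.5),
    archetype_spec("squat", 0.50, 6.0, c(0.30),
                   0.03, 0.08, 0.40, up, 0.5),
    archetype_spec("push_up", 0.60, 5.0, c(0.35, 0.10),
                   0.04, 0.10, 0.45, up, 0.5),
    archetype_spec("lunge", 0.45, 5.0, c(0.40),
                   0.05, 0.12, 0.50, up, 1),
    archetype_spec("crunch", 0.50, 3.5, c(0.55, 0.15),
                   0.06, 0.15, 0.55, tilt, 1),
    archetype_spec("bicep_curl", 0.80, 3.0, c(0.60),
                   0.06, 0.15, 0.55, side, 1),
    archetype_spec("elbow_extension", 0.70, 3.0, c(0.70, 0.20),
                   0.07, 0.18, 0.60, side, 1),
    archetype_spec("lower_trunk_rotation", 0.40, 2.5, c(0.85, 0.22),
                   0.08, 0.20, 0.60, up, 2),
    archetype_spec("bridge", 0.35, 2.0, c(0.90, 0.22),
                   0.10, 0.25, 0.65, tilt, 2),
    archetype_spec("upper_trunk_rotation", 0.45, 1.8, c(0.95, 0.25),
                   0.12, 0.30, 0.70, up, 2))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# rotate unit vector o about unit axis ax by angle theta (Rodrigues; ax
# chosen perpendicular to o, so the ax (ax.o) term vanishes)
.rotate <- function(o, ax, theta) {
  cross <- c(ax[2] * o[3] - ax[3] * o[2],
             ax[3] * o[1] - ax[1] * o[3],
             ax[1] * o[2] - ax[2] * o[1])
  o * cos(theta) + cross * sin(theta) + ax * sum(ax * o) * (1 - cos(theta))
}

.perp_axis <- function(o) {
  e <- if (abs(o[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ax <- c(o[2] * e[3] - o[3] * e[2],
          o[3] * e[1] - o[1] * e[3],
          o[1] * e[2] - o[2] * e[1])
  ax / sqrt(sum(ax^2))
}

#' Generate one synthetic exercise session
#'
#' Simulates a 3-axis accelerometer recording of one exercise bout with a
#' known true repetition count. Per-repetition periods are drawn with
#' multiplicative lognormal jitter around `1/rep_freq_hz` and rescaled so an
#' integer number of complete repetitions exactly fills the session (the
#' true count is the number of complete cycles; observers count whole
#' repetitions). The dynamic signal is a harmonic series in the within-rep
#' phase, with per-rep amplitude jitter, emitted along the (slowly drifting)
#' gravity orientation; standard gravity and white per-axis noise are added.
#' Output is deterministic for a fixed seed.
#'
#' @param spec an [archetype_spec()].
#' @param duration_s session length in seconds (default 30).
#' @param fs sampling rate, Hz; must be at least 4x the highest harmonic
#'   frequency.
#' @param seed integer seed.
#' @return Object of class `session_record`: list with `trace`
#'   (a [uniform_trace()]), `archetype`, `true_count`, `duration_s`, `seed`
#'   and the generating `spec`.
#' @examples
#' sp <- archetype_spec("demo", 1, 5)
#' sess <- generate_session(sp, duration_s = 30, fs = 50, seed = 1)
#' sess$true_count
#' @export
generate_session <- function(spec, duration_s = 30, fs = 50, seed = 1) {
  stopifnot(inherits(spec, "archetype_spec"))
  if (!(duration_s > 0)) stop("duration_s must be > 0")
  K <- 1 + length(spec$harmonic_weights)
  if (fs < 4 * spec$rep_freq_hz * K)
    stop("fs violates the Nyquist margin: need fs >= 4 * rep_freq_hz * ", K)
  set.seed(as.integer(seed))

  # per-rep periods: lognormal jitter with unit mean, then rescale so the
  # complete reps exactly fill [0, duration_s]
  base_T <- 1 / spec$rep_freq_hz
  n_draw <- ceiling(duration_s / base_T * 2) + 10L
  mult <- if (spec$freq_jitter_cv > 0) {
    sdlog <- sqrt(log(1 + spec$freq_jitter_cv^2))
    stats::rlnorm(n_draw, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, n_draw)
  periods <- base_T * mult
  cum <- cumsum(periods)
  R <- sum(cum <= duration_s + 1e-12)
  if (R < 1) stop("duration_s too short for a single repetition")
  periods <- periods[seq_len(R)] * (duration_s / cum[R])
  bounds <- c(0, cumsum(periods))
  bounds[R + 1] <- duration_s

  # per-rep amplitudes: Gaussian CV, truncated at +/- 3 SD
  amp_mult <- if (spec$amp_jitter_cv > 0) {
    a <- stats::rnorm(R, 1, spec$amp_jitter_cv)
    pmin(pmax(a, 1 - 3 * spec$amp_jitter_cv), 1 + 3 * spec$amp_jitter_cv)
  } else rep(1, R)
  amps <- spec$amplitude_ms2 * pmax(amp_mult, 0.05)

  n <- floor(duration_s * fs + 1e-9) + 1L
  tt <- (0:(n - 1)) / fs
  rep_idx <- pmin(pmax(findInterval(tt, bounds, rightmost.closed = TRUE), 1L), R)
  phase <- (tt - bounds[rep_idx]) / periods[rep_idx]
  wave <- sin(2 * pi * phase)
  if (K > 1)
    for (k in 2:K)
      wave <- wave + spec$harmonic_weights[k - 1] * sin(2 * pi * k * phase)
  dyn <- amps[rep_idx] * wave

  # gravity along a (possibly drifting) orientation; motion along the same axis
  if (spec$drift_deg_per_s != 0) {
    ax <- .perp_axis(spec$orientation)
    theta <- spec$drift_deg_per_s * pi / 180 * tt
    o <- vapply(theta, function(th) .rotate(spec$orientation, ax, th),
                numeric(3))
  } else {
    o <- matrix(spec$orientation, nrow = 3, ncol = n)
  }
  g <- 9.80665
  acc <- o * rep(g + dyn, each = 3)
  if (spec$noise_sd_ms2 > 0)
    acc <- acc + stats::rnorm(3L * n, 0, spec$noise_sd_ms2)

  trace <- uniform_trace(acc[1, ], acc[2, ], acc[3, ], fs = fs, t0 = 0)
  structure(list(trace = trace, archetype = spec$name, true_count = R,
                 duration_s = duration_s, seed = as.integer(seed),
                 spec = spec),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session '%s': %d reps in %g s @ %g Hz (seed %d)>\n",
              x$archetype, x$true_count, x$duration_s, x$trace$fs, x$seed))
  invisible(x)
}

# deterministic 31-bit child seed from (master, subject, archetype)
.child_seed <- function(master, i, j) {
  h <- (as.double(master %% 1000003L) * 8191 + i * 131071 + j * 524287) %%
    2147483629
  as.integer(h) + 1L
}

#' Generate a labeled synthetic benchmark
#'
#' A full study-style benchmark: every subject performs every archetype once.
#' Each subject's copy of an archetype gets independent uniform perturbations
#' (within +/- 20 percent) of repetition frequency, amplitude, noise level
#' and harmonic content, so subjects differ but remain recognisable. All randomness is
#' derived deterministically from the master seed via per-session child
#' seeds.
#'
#' @param archetypes list of [archetype_spec()] (default
#'   [default_archetypes()]).
#' @param n_subjects number of simulated subjects (default 18).
#' @param duration_s session length, seconds (default 30).
#' @param fs sampling rate, Hz (default 50).
#' @param seed master seed.
#' @return List of `n_subjects * length(archetypes)` `session_record`s; each
#'   carries a `subject` element.
#' @export
generate_benchmark <- function(archetypes = default_archetypes(),
                               n_subjects = 18, duration_s = 30, fs = 50,
                               seed = 1) {
  if (!(n_subjects >= 1)) stop("n_subjects must be >= 1")
  sessions <- vector("list", n_subjects * length(archetypes))
  idx <- 0L
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(archetypes)) {
      sp <- archetypes[[j]]
      cs <- .child_seed(seed, i, j)
      set.seed(cs)
      fac <- stats::runif(4, 0.8, 1.2)
      sp$rep_freq_hz <- sp$rep_freq_hz * fac[1]
      sp$amplitude_ms2 <- sp$amplitude_ms2 * fac[2]
      sp$noise_sd_ms2 <- sp$noise_sd_ms2 * fac[3]
      sp$harmonic_weights <- sp$harmonic_weights * fac[4]
      sess_seed <- sample.int(2147483646L, 1)
      sess <- generate_session(sp, duration_s = duration_s, fs = fs,
                               seed = sess_seed)
      sess$subject <- i
      idx <- idx + 1L
      sessions[[idx]] <- sess
    }
  }
  sessions
}
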