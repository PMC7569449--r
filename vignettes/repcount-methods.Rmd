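---
title: "Counting exercise repetitions without training: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting exercise repetitions without training: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repcount)
```

## The problem

Home physical-therapy programmes prescribe repetitive exercises — squats,
arm circles, trunk rotations — and adherence is hard to verify. A smartphone
or wearable accelerometer strapped to (or held by) the patient records the
motion, but most activity-recognition pipelines must be trained per
movement, which is impractical when exercises are tailored to an individual
patient. `repcount` implements a deliberately training-free alternative:
three simple counting methods that exploit only the periodicity of the
signal, applicable to any repetitive motion without labelled data.

## Signal model and preprocessing

A recording is a 3-axis acceleration trace $a_k = (x_k, y_k, z_k)$ in
m/s$^2$ (values in g are converted on load; 1 g = 9.80665 m/s$^2$).
Timestamped input is linearly interpolated onto a uniform grid
(`resample_uniform()`, default 50 Hz — phone-class accelerometers sample at
tens of Hz, which oversamples any plausible repetition rate of 0.2–2 Hz, so
interpolation order is immaterial for crossing counts and spectral peaks).
Non-exercise data at the ends of a bout is removed with `trim()`.

Counting operates on a scalar. The obvious reduction, the magnitude
$\lVert a_k \rVert$, is always positive: the negative half of each
oscillation folds onto the positive half (half-wave rectification), which
doubles apparent crossing rates and corrupts the spectrum. `repcount`
therefore restores a sign from the gravity direction. A centered moving
average over `gravity_window_s` seconds (default 2 s; edge-truncated, so no
phase lag) estimates the slowly varying gravity-plus-posture baseline $g_k$.
With $d_k = a_k - g_k$ the dynamic component and
$\hat g_k = g_k / \lVert g_k \rVert$,

$$ s_k \;=\; \operatorname{sgn}(d_k \cdot \hat g_k)\,\lVert d_k \rVert, $$

with $\operatorname{sgn}(0) = +1$ and a $+1$ fallback where the gravity
estimate is zero. Motion along gravity is positive, motion against it
negative: for axial motion $a_k = g + c(t_k)\hat g$ this recovers the signed
oscillation $c(t)$ itself, negative half-waves included (verified to 1% of
amplitude in the window interior by the test suite). The window default of
2 s exceeds the half-cycle of any plausible repetition while still tracking
slow orientation drift; the signed-raw-magnitude variant
(`sign_mode = "raw"`, which signs $\lVert a_k \rVert$ instead of
$\lVert d_k \rVert$) is retained as a configuration option, but since the
raw magnitude is gravity-dominated it almost never goes negative and does
not de-rectify anything — `dynamic` is the default because it achieves the
stated purpose of the sign step.

## The three counters

**Threshold crossing** (`count_threshold()`). The threshold is
range-relative: $\tau = \min s + \lambda (\max s - \min s)$ with
$\lambda =$ `threshold_frac` (default $2/3$). One repetition is counted at
each upward crossing ($s_{k-1} < \tau \le s_k$; a sample sitting exactly on
$\tau$ counts once, deterministically). After a counted crossing, further
crossings within the refractory period `refractory_s` (default 0.1 s) are
suppressed — multi-peaked repetitions would otherwise double-count.
Suppressed crossings do not restart the refractory clock: the period exists
to prevent extra counts, not to delay legitimate ones. A degenerate series
(range $< 10^{-9}$ m/s$^2$) yields count 0. Because $\tau$ is
range-relative, all three methods are invariant to positive rescaling of
the signal.

**Threshold crossing with low-pass filtering**
(`count_threshold_lowpass()`). Identical, applied to the output of a
first-order recursive (exponentially weighted) low-pass filter

$$ A_i = (1 - \alpha) A_{i-1} + \alpha X_i, \qquad \alpha = 0.1
   \text{ by default}, $$

initialised at $A_1 = X_1$ to avoid a startup transient; the threshold is
recomputed on the filtered signal. The unit-impulse response is
$\alpha(1-\alpha)^{n-1}$, exposed through the `init` argument and checked
in closed form by the tests. At 50 Hz and $\alpha = 0.1$ the $-3$ dB point
sits near 0.9 Hz: repetition-rate components pass with mild attenuation
while sample-scale noise power drops by roughly $\alpha/(2-\alpha) \approx
0.05$, which is what rescues threshold counting on noisy signals.

**Fourier dominant frequency** (`count_fourier()`). The mean is removed,
the magnitude spectrum computed, and the dominant frequency $f^*$ taken as
the spectral argmax over `band_hz` (default 0.2–5 Hz — plausible human
repetition rates, excluding DC and tremor-band noise). The count is
$f^* T$ with $T = (n-1)/f_s$, rounded half-up to an integer
(`round_mode = "floor"` is available; counts are reported as integers
because human observers count whole repetitions). Ties in the argmax break
toward the *lower* frequency, which avoids locking onto a harmonic of the
true rate.

### Numerical choices and degenerate inputs

- Duplicate timestamps keep the first occurrence (deterministic,
  order-preserving); non-finite rows are dropped with a warning.
- `trim()` uses a closed interval with a relative $10^{-9}$ tolerance so
  grid points on the boundary are kept regardless of floating-point
  representation of the grid.
- Degenerate (constant) series: threshold counters return 0 via the
  range test; the Fourier counter returns 0 when the in-band spectrum is
  identically zero, and warns when the band contains no bin at all.
- The threshold fraction default of $2/3$ of the range is one published
  convention among several; it is deliberately a plain configuration value,
  and `tune_threshold()` performs the grid search (default grid 0.05–0.95
  in steps of 0.05, ties toward the smaller fraction) for anyone who wants
  a data-driven choice on a labelled convenience sample.

## The synthetic session generator

Real labelled recordings of this kind are not redistributable, so the
package ships a generator (`generate_session()`, `generate_benchmark()`)
that produces traces with *known* true counts. One session is

$$ a(t) = 9.80665\,o(t) \;+\;
   \Big[ a_r \sum_{k=1}^{K} w_k \sin(2\pi k \varphi_r(t)) \Big] o(t)
   \;+\; \varepsilon(t), $$

where $o(t)$ is a unit orientation rotating at `drift_deg_per_s` (posture
drift), $\varphi_r$ is the within-repetition phase, $w_1 = 1$ with
`harmonic_weights` for $k \ge 2$, and $\varepsilon$ is white Gaussian
noise per axis. Per-repetition periods get multiplicative lognormal jitter
(CV `freq_jitter_cv`; lognormal keeps periods positive) and amplitudes
$a_r$ get Gaussian jitter truncated at $\pm 3$ SD (CV `amp_jitter_cv`).
The drawn periods are rescaled so an integer number of complete
repetitions exactly fills the session; the true count is that integer
(observers count completed repetitions, and with zero jitter the count
reduces to $\lfloor f D \rfloor$ exactly). The dynamic component is emitted
along the gravity axis so the sign-restoration step is exercised as
designed. Everything is deterministic given the seed; benchmark child
seeds are a fixed hash of (master seed, subject, archetype).

### Archetype calibration

Ten built-in archetypes (`default_archetypes()`) span the difficulty
gradient observed in real exercise data: large periodic motions (arm
circles at 1 Hz and 8 m/s$^2$ peak, squats, push-ups) are easy for every
method; small irregular motions (bridge, upper trunk rotation at
1.8–2 m/s$^2$ with strong jitter and noise) are hard. The parameters are
the package's own calibration — plausible magnitudes, not measurements —
chosen so each method fails for the reason it fails in practice:

- raw threshold crossing degrades with noise: near the threshold, noise
  produces bursts of spurious upward crossings that the refractory period
  only partially caps;
- the low-pass variant removes most of that noise and stays accurate;
- the Fourier method is immune to white noise but vulnerable to *harmonic
  capture*: motions with two acceleration peaks per cycle (second-harmonic
  weight near 1, as in the hard archetypes) can hand the spectral argmax
  to $2f$, doubling the count. Period jitter broadens the harmonic line
  faster than the fundamental, so capture is occasional rather than
  systematic.

Under this calibration the seeded 18-subject × 10-archetype benchmark
(`generate_benchmark(seed = 20201010)`, 30 s sessions at 50 Hz) reproduces
the qualitative ordering expected of the three methods — filtered
threshold best, Fourier intermediate, raw threshold worst, and every
method better on arm circles than on upper trunk rotations. The test suite
asserts exactly this, and `scripts/acceptance.R` recomputes the pooled
RMSEs from scratch.

What the generator does *not* emulate: rest pauses and mixed activities
within a bout, amplitude decay from fatigue, sensor bias/clipping, and
non-axial motion geometry. Passing the benchmark therefore shows the
counters behave correctly on controlled periodic-plus-noise structure; it
is not a claim about every failure mode of field recordings.

## Evaluation protocol

`rmse()` scores a method over sessions as
$\sqrt{\tfrac1n \sum_i (\hat C_i - C_i)^2}$ in counts.
`evaluate_sessions()` reports an exercise × method RMSE matrix plus two
averages: the **pooled RMSE** over all sessions (the primary summary — a
single estimator over the pooled squared errors) and the mean of the
per-exercise RMSEs (reported alongside because the two aggregations
genuinely differ; for squared errors 9 and 16 in two one-session exercises
they give $\sqrt{12.5} \approx 3.54$ versus $3.5$). Sessions whose
participant and observer counts disagree are excluded when loading a
manifest (`read_manifest()`): disagreement means the ground truth itself is
unreliable.

## Problem sizes

The shipped tests and the acceptance script use 30 s sessions at 50 Hz
(1501 samples), the full 18 × 10 benchmark (180 sessions) for the ordering
checks, and 1000 short random signals for the crossing-counter equivalence
check; the complete suite runs in a few seconds on one core.

## Known limitations

- One activity per bout: mixed or interrupted activity streams are out of
  scope, as is rest-period detection.
- The Fourier count is global: tempo changes within a bout blur the
  dominant peak.
- The gravity proxy is a moving average, not an orientation filter; very
  fast posture changes (faster than the window) leak into the dynamic
  component.
- Archetype parameters are synthetic stand-ins; conclusions about specific
  real exercises require real labelled data.
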