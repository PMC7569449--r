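# repcount

Training-free counting of exercise repetitions from 3-axis accelerometer
recordings.

Home physical-therapy exercises are often unique to a patient, so
activity-recognition models that must be trained per movement are of little
use for tracking them. `repcount` counts repetitions of *any* repetitive
motion recorded by a smartphone or wearable accelerometer, using only the
periodicity of the signal — no labelled training data, no per-exercise
tuning.

## Method

A trace is resampled to a uniform grid and reduced to a **signed
acceleration magnitude**: with gravity baseline `g_k` (long-window moving
average) and dynamic component `d_k = a_k − g_k`,

```
s_k = sgn(d_k · ĝ_k) · ‖d_k‖        (ĝ_k = g_k / ‖g_k‖)
```

so motion along gravity is positive and motion against it negative —
avoiding the half-wave rectification a plain magnitude would cause. Three
interchangeable counters then estimate the repetition count `C`:

1. **Threshold crossing** — count upward crossings of
   `τ = min(s) + λ·range(s)` (default `λ = 2/3`), with a 0.1 s refractory
   period suppressing multi-peak double counts;
2. **Threshold crossing + low-pass** — the same after the first-order
   recursive filter `A_i = 0.9·A_{i−1} + 0.1·X_i`;
3. **Fourier** — `C = round(f* · T)` where `f*` is the dominant spectral
   frequency in 0.2–5 Hz and `T` the duration.

A synthetic session generator with known true counts, an RMSE-of-counts
evaluation harness and a grid-search threshold tuner complete the package.

## Worked example

```r
library(repcount)

# simulate one squat-like bout: 0.5 Hz, 6 m/s^2 peak, mild jitter and noise
sp <- archetype_spec("demo_squat", rep_freq_hz = 0.5, amplitude_ms2 = 6,
                     harmonic_weights = 0.3, freq_jitter_cv = 0.03,
                     amp_jitter_cv = 0.08, noise_sd_ms2 = 0.4)
sess <- generate_session(sp, duration_s = 30, fs = 50, seed = 42)
sess
#> <session 'demo_squat': 14 reps in 30 s @ 50 Hz (seed 42)>

s <- preprocess_trace(sess$trace)   # signed magnitude series
res <- count_reps(s, "all")
for (r in res) print(r)
#> method: threshold
#> count: 26
#> duration_s: 30.000
#> threshold_used: 2.5239 m/s^2
#> method: threshold_lowpass
#> count: 14
#> duration_s: 30.000
#> threshold_used: 1.7732 m/s^2
#> method: fourier
#> count: 14
#> duration_s: 30.000
#> dominant_freq_hz: 0.4664
```

The true count is 14. Raw threshold crossing overcounts (26) because noise
near the threshold triggers spurious crossings; after low-pass filtering the
count is exact, and the Fourier estimate (0.466 Hz × 30 s ≈ 14) agrees.

Recorded data works the same way: `read_trace("bout.csv", unit = "g")` →
`resample_uniform()` → `count_reps()`. A thin command-line wrapper is
installed at `system.file("cli", "repcount.R", package = "repcount")` with
`count`, `simulate` and `evaluate` subcommands.

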