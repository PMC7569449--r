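Package: repcount
Title: Training-Free Repetition Counting from Triaxial Accelerometer Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts repetitions of arbitrary periodic exercise motions from
    smartphone or wearable 3-axis accelerometer recordings without any
    exercise-specific training. A recording is reduced to a signed scalar
    acceleration magnitude (the gravity direction restores the sign,
    avoiding half-wave rectification of the oscillation) and counted by
    three interchangeable methods: upward threshold crossing with a
    refractory period, the same after a first-order recursive low-pass
    filter, and dominant-frequency counting from the Fourier spectrum.
    Includes a synthetic exercise-session generator with known ground-truth
    counts, an RMSE-of-counts evaluation harness with per-exercise and
    pooled summaries, grid-search tuning of the threshold fraction, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
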