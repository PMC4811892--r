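Package: vwpupil
Title: Visual-World Eye-Tracking and Pupillometry Pipeline for Natural and
    Vocoder-Degraded Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying lexical competition in natural and
    cochlear-implant-simulated (sinewave-vocoded) speech with the
    visual-world paradigm. Implements a Greenwood-spaced eight-channel
    sinusoid vocoder, cross-splicing of durational cues, preprocessing of
    250-Hz gaze and pupil traces (blink detection and interpolation, trial
    and participant screening, event-related pupil dilation under per-trial
    and session-start baselines), fixation-proportion time courses with
    confidence bands and target/competitor crossover detection, orthogonal
    polynomial growth-curve analysis with participant random effects and
    sequential likelihood-ratio model comparison, and a synthetic-session
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
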