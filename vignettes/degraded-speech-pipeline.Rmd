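---
title: "Methods: lexical competition in natural and vocoder-degraded speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexical competition in natural and vocoder-degraded speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwpupil)
```

## The problem this package addresses

When listeners hear the first syllable of *bokser* ("boxer"), the embedded
word *bok* ("goat") is briefly a live lexical candidate. In natural speech,
boundary lengthening makes a free-standing monosyllable some 20–120 ms
longer than the same syllable embedded in a longer word, and listeners use
that durational cue to settle the competition quickly. Cochlear implants
transmit a spectrally degraded signal but preserve durations, which makes
this cue a clean probe of how degradation affects the *timing* of lexical
access. The experimental paradigm combines visual-world eye-tracking
(fixations to a target picture, its phonological competitor, and two
distractors track the competition in real time) with pupillometry (slow
pupil dilation indexes mental effort).

`vwpupil` implements the complete computational chain of such a study —
stimulus construction, acoustic degradation, ocular-trace preprocessing,
fixation and pupil time-course analysis, growth-curve modeling — together
with a synthetic-data generator with known ground truth, so the whole chain
can be validated end to end without human data.

## Acoustic simulation (sinewave vocoder)

The degradation is an eight-channel sinewave vocoder. The band edges are
spaced so that their positions on the basilar membrane, under the Greenwood
frequency–position map `F(x) = A(10^(a·x) − k)`, form an arithmetic
sequence from 100 Hz to 10 kHz. The map's constants are not part of the
published processing description; we use the standard human
parameterization `A = 165.4` Hz, `a = 2.1`, `k = 0.88` (exposed in
`greenwood_map()`). Per band, the temporal envelope is extracted by
half-wave rectification followed by a 4th-order Butterworth low-pass at
300 Hz, and the band is resynthesized as a sinusoid at the band's center
frequency (defined as the Greenwood midpoint of the band; geometric and
arithmetic means are available as options) modulated by that envelope.

Choices the processing description leaves open, fixed here:

* The analysis band-pass filters are 4th-order Butterworth, applied
  forward–backward (zero phase) so that splice timing is not shifted;
  order and phase mode are configurable (`band_order`, `zero_phase`).
* Carrier phase is zero at signal start — deterministic, no seed.
* Inputs sampled below `2·f_hi` are rejected, never silently resampled.

Vocoding conserves the sample count exactly, which is the property the
paradigm depends on: the durational cue must survive degradation untouched.

## Stimulus construction

Each critical item exists as three synthetic "recordings": two renditions
of the polysyllabic sentence and one of the monosyllabic sentence, built by
`synthesize_token()` as harmonic complexes with a −6 dB/octave tilt, an
amplitude contour, and a marked splice boundary. `cross_splice()`
concatenates the first part of one token with the second part of another,
sample-exactly; cuts snap to the nearest zero crossing to avoid clicks (an
engineering choice — disable with `snap_to_zero = FALSE` for bit-exact
boundary placement). Condition 1 (target-matching cues) splices
polysyllabic onto polysyllabic; Condition 2 (target-mismatching cues) puts
the longer monosyllabic first part before the same continuation.

The default inventory holds 26 critical pairs and 40 fillers (7
polysyllabic / 33 monosyllabic; 20 competitor-free, 10 initial-embedding,
10 final-embedding). Duration differences are drawn from a Beta(2.25, 2.75)
scaled to [20, 120] ms, whose mean is exactly 65 ms — a uniform on the
stated range would force a mean of 70 ms and was therefore rejected.

## Ocular preprocessing

Traces are 250-Hz samples of gaze position, pupil area and validity.
The screening rules, in order:

* a trial whose click did not land on the target is excluded;
* a blink (maximal run of invalid/zero-pupil samples) of 300 ms or longer
  excludes the trial — exactly 300 ms is assigned to the exclusion side,
  the conservative reading of a rule stated as "shorter than 300 ms are
  interpolated / longer than 300 ms are excluded";
* shorter blinks are repaired by the line joining the medians of the 25
  samples before and after the gap (medians make the anchors robust to
  spikes); a blink without 25 valid context samples on each side excludes
  the trial rather than being padded;
* a participant whose exclusions reach 50% of trials is dropped.

%ERPD is `(observation − baseline)/baseline × 100` under two baselines:
baseline 1, the mean pupil over the 200 ms before the target word
(per trial); baseline 2, the mean pupil over the 200 ms at the very start
of the experiment, which we anchor immediately before the first sentence's
audio onset (one value per participant). Analysis windows are half-open
`[start, end)` with 0-based sample indexing throughout: 200–2000 ms after
word onset (450 samples at 250 Hz) for pupil analyses and fixation counts,
200–1800 ms for the fixation growth curves, both exposed as parameters.

## Fixation analysis

The display is a 3×3 grid; pictures sit in the four corner quadrants and a
cross in the center. A picture's area of interest is its full quadrant
(matching the quadrant-centered layout); edge cells and off-screen samples
map to `none`. Proportion-of-fixation curves average per-participant
proportions, with a 95% normal-approximation confidence band over
participant means (the reference analyses do not state their CI
construction; a bootstrap would be a drop-in alternative). The
target/competitor crossover — the moment the target has, on average, won
the competition — is defined as the first time the target curve exceeds
the competitor curve and stays strictly above it for 100 ms; a persistence
window makes the quantity well-defined on noisy curves, and `NA` is
returned when no persistent crossing exists. The lowess smoother
(`smooth_curve()`, tricube local linear regression, span 0.5) is for
display only and never feeds statistics.

## Growth-curve analysis

Time courses are regressed on polynomials orthonormalized over the
*observed* grid (QR factorization of the raw powers, as in `stats::poly`,
plus a unit-norm constant column): intercept, slope, rise-and-fall
(quadratic), tail steepness (cubic), and a quartic where applicable. The
per-sample binary competitor-fixation indicator is modeled with a logistic
link at order 4 over 200–1800 ms; %ERPD with an identity link at order 3
over 200–2000 ms. Both include participant random coefficients on all
basis terms. Estimation is maximum likelihood via `lme4`; the logistic
case uses the Laplace approximation to the marginal likelihood, and the
identity-link / no-random-effects degenerate limits are verified in the
test suite against ordinary least squares and a direct likelihood
optimization. Mixed fits that end on the boundary of the random-effect
variance space (singular fits) are reported as converged; optimizer
failures are flagged and sequential results carry the flag.

Model comparison follows the sequential ladder: starting from the
basis-only model, each block of the factor expansion (factor main effects
on the intercept, then the factor × slope interactions, and so on) is
added in turn and assessed by a likelihood-ratio test,
`χ² = 2·Δ logLik` with the parameter-count difference as degrees of
freedom. The default ladder (`gca_ladder()`) adds one curve term per
block; any ordering can be supplied, since nested-pair choices beyond the
default are a reporting convention rather than a statistical necessity.
The per-sample binary response is the default because the source analyses
say "logistic growth curves" without stating an aggregation; an aggregated
response can be fitted by passing a preprocessed data frame.

## The synthetic-data generator

The generator is first-class, tested code: it encodes the study conditions
as defaults — 62-trial sessions with 26 critical trials (13 per condition;
the counterbalancing split is not stated in the protocol and 13/13 is the
balanced choice), 250-Hz traces, 95% correct clicks, and an inventory of
66 items reconciled to 62 trials by sampling 36 of the 40 fillers.

**Ground truth.** Per condition, target/competitor/distractor/cross
activation curves over time (logistic rise for the target; logistic
rise-and-fall for the competitor) are normalized into AOI occupancy
probabilities, and a %ERPD template (relative to the session-start
baseline) gives the pupil trajectory. The target-mismatching condition is
the target-matching condition with the competition dynamics delayed by a
fixed shift — 120 ms in the `NS` preset, 240 ms in the `DS` preset — so
the generated crossover offset *is* the shift, exactly. The `DS` preset is
additionally shallower and delayed overall, with a flat elevated
session-baseline ERPD and a per-trial bump of smaller amplitude; the `NS`
ERPD template peaks 1100 ms after word onset. These presets encode the
qualitative signature of degraded-speech processing as generator settings,
not as claims of reproducing any particular dataset.

**Gaze process.** Gaze is a sequence of fixation dwells. A naive process
that samples an AOI once per dwell smears the pooled occupancy curves by
the dwell length, which both biases them away from the generating curves
and flattens the crossover region. We therefore use quantile-coupled
dwells: each dwell carries one latent uniform draw, and at every sample
the AOI is the quantile category of that uniform under the cumulative
occupancy probabilities at that instant. The per-sample occupancy marginal
then equals the generating curve exactly (pooled curves are unbiased at
every time point), while gaze persistence — and hence realistic fixation
structure — comes from holding the uniform within a dwell. The latent
dwell mean (1500 ms, gamma shape 4) is calibrated so the 200–2000 ms
window contains on average three observed fixations (mean observed
fixation duration ≈ 600 ms), matching the reference figure; observed
fixations are shorter than latent dwells because the evolving curves
themselves move gaze mid-dwell.

**Pupil process.** Pupil = participant baseline × (1 + template/100),
plus AR(1) noise (ρ = 0.97 at 250 Hz, SD ≈ 0.6% of baseline — slow
physiological drift; no noise figures are published, so these are
realistic free parameters) and Poisson blinks (0.3 per trial, log-normal
durations, meanlog log(150), sdlog 0.5, putting ≈ 8% of blinks at or past
the 300-ms exclusion threshold, i.e. a few excluded trials per session).
Because the template is encoded multiplicatively, %ERPD computed from a
noiseless trace recovers the template to machine precision — the
generative inverse the preprocessing tests rely on.

**What the generator does not emulate.** Saccade kinematics and the
oculomotor main sequence; visual saliency of specific pictures; luminance
responses; item-level variability (the statistical models accordingly use
participant random effects only, as in the reference analyses). Passing
tests therefore validate the *pipeline mechanics and statistical
machinery*, not claims about human data; the published test statistics
depend on participant data that is not deposited and are out of scope by
design.

## Numerical choices and problem sizes

* Filters run forward–backward; signals shorter than the filter warm-up
  are rejected with an explicit error.
* Convergence handling for mixed fits: `lme4` defaults (relative
  tolerances ~1e-6); singular boundary fits count as converged.
* Windows are half-open everywhere; ties at window edges therefore have
  one defined owner.
* The end-to-end crossover validation uses 400 simulated NS participants
  and 60 DS participants: with ~13 critical trials per condition per
  session, this puts the Monte-Carlo standard error of the recovered
  crossover offset near 7 ms, small enough to resolve the generated
  120-ms offset to sample precision (±20 ms at the 250-Hz grid). Null
  calibration of the LRT ladder uses 100 replicates of 16 participants;
  parameter recovery uses 100 replicates of 30 participants — sizes at
  which the χ² asymptotics of likelihood-ratio tests for fixed effects
  are adequate.
* All randomness descends from one root seed; sessions are bit-identical
  under the same configuration.

## Known limitations

* The vocoder implements sinusoid carriers only — no noise-band carriers,
  current-spread or compression models of real implant processors.
* `NA` crossovers are possible on flat or noisy curves by design; callers
  must handle them.
* The logistic growth-curve models use the Laplace approximation;
  quadrature would be preferable for very small participant counts.
* Reading device-native eye-tracker binaries is out of scope; the TSV
  dialects documented in `?ocular_io` are the interchange format.
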