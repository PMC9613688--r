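---
title: "Methods: dual-task saccade and posture assessment with oculosway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-task saccade and posture assessment with oculosway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oculosway` models a concurrent assessment paradigm in which standing
balance (centre-of-pressure, COP, on a force platform) and saccadic eye
movements (gaze angle from a VR eye tracker) are recorded simultaneously
while cognitive load is manipulated. This vignette documents the models,
conventions and numerical choices behind each stage, and what the
simulation-based tests do and do not establish about real recordings.

## The experimental protocol

Eleven conditions form the battery (`condition_table()`): eyes-open and
eyes-closed stances without a headset, a gaze-only 2D control, and
pro-/anti-saccade tasks in four environments — plain 2D, a visually
challenging 3D scene, a visuospatial-memory (VM) task and a
spatial-orientation (SO) frame-switching task. Every condition loads
posture; conditions 4–11 form a complete 4 (environment) × 2 (task)
within-subject factorial.

`build_schedule()` realizes each condition's cycle structure:

| environment | cycle | frames | practice | recorded |
|---|---|---|---|---|
| 2D / 3D | 2 s | 1 s fixation, 1 s target at ±8° | 10 | 30 |
| SO | 7.5 s | 2.5 s fixation, 2.5 s allocentric/egocentric view (markers at ±2°), 2.5 s response at ±8° | 5 | 15 |
| VM | 10 s | 2.5 s fixation, 2.5 s memorise (two distinct symbols at ±2°), 2.5 s fixation, 2.5 s response at ±8° | 5 | 15 |

Posture recording starts at the end of the last practice cycle; the
stimulus stream is seamless so a subject cannot tell where recording
begins.

**Side balance.** Target sides are a seeded permutation of a balanced
multiset with at most three consecutive repeats (anticipation
mitigation; configurable via `max_run`). Thirty recorded trials split
15/15. Fifteen recorded trials cannot split evenly, so the recorded
trials split 8/7 with a seed-determined majority and the practice trials
take the opposite extra (3/2), making every schedule exactly balanced
overall. This is the package's resolution of an under-determined design
point: "equal numbers of left and right targets" is enforced at the
schedule level, and as nearly as parity allows within the recorded
subset.

**Open points decided.** The 2D/3D target stays visible for the whole
1 s response window (`target_full_window = TRUE`); the printed protocol
constrains the response deadline, not stimulus offset, and a visible
target is the conservative choice for gaze-duration analyses. The VM
memorise frame is encoded as a single event carrying the probe symbol
and side plus the distractor (`symbol_other`), keeping event onsets
strictly increasing. In the SO environment the inner allocentric map
shows the circle/square markers at ±2° and the egocentric goal sits at
±8° on the same side as the circle.

## The simulator

`subject_model()` collects per-subject parameters; the defaults describe
a healthy older adult and are the package's study conditions, not tuning
knobs:

* **Latency**: shifted log-normal with an 80 ms physiological floor;
  defaults mean 250 ms, SD 50 ms. Draws at or beyond the response window
  are redrawn and counted (`n_redraws`).
* **Directional errors**: the primary saccade goes opposite to the
  expected direction with probability `error_prob` (default 0.08–0.1 in
  the demo cohort; anti-saccade and VM/SO loads add to it in
  `run_config()`'s effect structure).
* **Kinematics**: the main-sequence law `v_peak = v_max (1 − e^{−A/c})`
  with `v_max = 500` deg/s and `c = 6°`; an 8° saccade peaks at
  368.2 deg/s. The displacement profile is a logistic sigmoid truncated
  to the duration convention `2.2 ms/deg × A + 21 ms`; the slope
  constant is solved by fixed-point iteration so that the *realized*
  peak velocity of the truncated, rescaled profile equals the
  main-sequence value exactly (a plain `4 v_p / A` slope would overshoot
  by the truncation factor, ~6% at 8°).
* **Intrusions**: saccadic intrusions are out–hold–back excursions with
  amplitudes 0.3–0.8°, injected as a Poisson process with a 250 ms
  refractory gap so that two intrusions never superpose into a
  supra-degree excursion the detector would rightly report.
* **COP**: two independent Ornstein–Uhlenbeck processes (relaxation θ,
  diffusion D), exactly discretized and started from the stationary
  distribution, so the per-axis SD is `√(D/2θ)` from the first sample.
  Defaults θ = 1 s⁻¹, D = 10 mm²/s give a ~2.2 mm stationary spread,
  typical of quiet stance.
* **Pupil**: baseline + sinusoid + white noise (defaults 3.5 mm,
  0.1 mm at 0.5 Hz, 0.02 mm noise).

Sampling rates default to 120 Hz (gaze) and 100 Hz (COP); device rates
are conventions here, both configurable. All generators are
bit-reproducible under a fixed seed.

What the simulator does **not** emulate: smooth pursuit, vergence, head
motion, pupil foreshortening artefacts, platform drift, or any
non-stationarity of sway. Passing the recovery tests therefore shows the
*pipeline* is correct and well-calibrated on signals with known truth;
it does not validate the physiological realism of any parameter.

## Saccade detection and scoring

Detection (`detect_saccades()`) estimates velocity by central
differences, smooths with a symmetric 3-sample moving average, and takes
contiguous runs of 2-D speed ≥ 30 deg/s lasting ≥ 10 ms as candidates.
Onsets/offsets refine to the interpolated threshold crossing, and the
onset additionally refines to the interpolated crossing of a 0.5°
departure from the pre-saccadic median baseline (accepted only within
3 samples of the velocity crossing). The position-based stage matters at
consumer sampling rates: with 0.3° gaze noise at 120 Hz, velocity-only
onsets jitter by roughly a sample (~8 ms), while the position crossing
of an 8° movement is nearly noise-free; the symmetric smoothing window
is zero-phase, so neither stage biases onsets systematically. Events
with |horizontal displacement| < 1° are discarded as non-saccadic — the
intrusion-exclusion rule — with the displacement measured between short
averages just outside the event.

Scoring (`score_trials()`) takes the first detected saccade after each
response-frame onset: latency, peak speed and direction come from that
saccade; later corrective saccades are ignored, and an initial
wrong-direction saccade marks the trial incorrect even if corrected
(standard anti-saccade convention). Saccades earlier than the 80 ms
anticipation floor invalidate the trial (`anticipatory`) rather than
counting as errors — they are predictive, not reactive. Windows without
a qualifying saccade are `no_saccade`; invalid-sample gaps over 100 ms
are `data_gap` (shorter gaps are bridged by linear interpolation). In
the VM/SO tasks correctness uses the gaze-duration rule
(`gaze_duration_target()`): the side whose ±3° region of interest around
the ±8° target collects strictly the longest dwell is the selected
target; equal nonzero dwells are a flagged tie scored as no selection.
The first-saccade direction is recorded alongside for comparison.

`aggregate_condition()` reports means and sample SDs (n−1) of latency
and peak speed over valid trials and the error rate, whose denominator
is the valid-trial count by default; a printed error rate could equally
be per all trials, so both denominators are exposed
(`denominator = "all"`).

## Posturography

`compute_posture_metrics()` computes per-axis displacement SDs, mean
sway speed as path length over duration (total Euclidean and per-axis
absolute steps), and the sway area of the envelope curve (AEC). "Envelope
curve" is interpreted as the convex hull of the COP trajectory — the
standard outer-envelope convention in stabilometry — built by the
monotone-chain algorithm with the shoelace area. Degenerate trajectories
(fewer than three non-collinear points) have zero area and are flagged.
No filtering is applied by default (platform output is assumed
conditioned). The analysis window for scheduled conditions starts where
posture recording starts (after the practice trials); the eyes-open/
closed baselines use 60 s. Units are millimetres throughout; cm-declared
files are converted on read.

## Pupil spectral summary

`pupil_psd()` removes a linear trend, averages Hann-windowed one-sided
periodograms over 50%-overlapping segments (Welch), and rescales the
spectrum so it integrates exactly to the variance of the de-trended
series. That normalisation makes band summaries comparable across
recordings of different lengths and guarantees Parseval consistency;
the band mean defaults to 0.05–2 Hz, where task-evoked pupil
oscillations live. A constant series returns an all-zero spectrum.

## Statistical battery

Conditions 4–11 form the factorial analyses; the long table is
(subject, condition, parameter, value).

* `check_distributions()`: Levene in the Brown–Forsythe form (absolute
  deviations from group medians) across conditions, and Shapiro–Wilk on
  pooled residuals. These justify the nonparametric pipeline.
* `rank_factorial_anova()`: aligned-rank-transform two-way
  repeated-measures ANOVA. For each effect the response is aligned (all
  other estimated effects removed via cell means), ranked across the
  whole sample, and a within-subject ANOVA is fitted on the ranks with
  subject error strata; only the aligned effect's p value is retained.
  Aligned values equal to 10 significant digits are treated as tied so
  floating-point noise in the alignment cannot break exact ties; an
  effect with literally zero aligned variation reports F = 0, p = 1.
  Under a 20-subject null simulation the environment and task main
  effects reject at 5.2–5.5% (nominal 5%); a 5σ environment shift is
  detected at p < 0.001 with power ≈ 1. `friedman_main_effects()` offers
  a simpler per-factor cross-check.
* `wilcoxon_pairwise()` / `wilcoxon_signed_rank()`: paired signed-rank
  tests over the post hoc scheme (same task across environments, same
  environment across tasks; 16 pairs). Zero differences are dropped by
  default (Wilcoxon's rule; Pratt optional). The exact null distribution
  is used for ≤ 25 untied nonzero differences, otherwise a tie- and
  zero-corrected normal approximation with continuity correction. The
  effect size is `r = |Z|/√n_pairs`, labelled small/moderate/large at
  0.1/0.3/0.5; Z always comes from the corrected normal form so r is
  defined for exact tests too. Holm adjustment (uniformly more powerful
  than Bonferroni, no independence assumption) is applied within each
  parameter's family of comparisons.
* `spearman_matrix()`: tie-corrected Spearman correlations between
  parameters within one condition, two-sided p values, significance
  flagged at 5% unadjusted (exploratory highlighting); constant columns
  are masked as undefined.

## Problem sizes and determinism

The test-suite simulations use the battery's own scales: 30-trial
sessions at 120 Hz, 600 s COP runs for stationary-moment recovery,
200 sessions for error-rate coverage, 1000 null replicates for ANOVA
calibration, and a 20-subject × 11-condition demo cohort, which runs in
about two minutes and writes byte-identical outputs under a fixed seed
(per-subject/condition/stream seeds derive deterministically from the
master seed; run logs carry the seed and a config hash, and no
timestamps).

## Known limitations

* The simulator's gaze returns to centre with a fixed 200 ms
  re-fixation delay; express re-fixations and multi-step returns are not
  modelled.
* Peak-speed estimates at 120 Hz underestimate the true peak of a
  ~40 ms saccade (finite-difference smearing); tests that assert 2%
  peak-speed accuracy sample at 1000 Hz. Latency is robust at 120 Hz;
  peak-speed comparisons across conditions remain valid because the bias
  is shared.
* The AEC convention (convex hull) differs from proprietary
  platform-internal definitions; values are comparable within the
  package, not across devices.
* The exact normalisation behind any particular printed pupil PSD value
  is device- and pipeline-specific; the variance normalisation here is a
  documented convention.
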