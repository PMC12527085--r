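---
title: "Detecting and segmenting Sit phases from a single ankle-worn IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and segmenting Sit phases from a single ankle-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sitseg)
```

## The problem

People with Parkinson's disease transition in and out of chairs many times a
day, and the frequency and duration of seated (*Sit*) phases — bounded by a
stand-to-sit transition at onset and a sit-to-stand transition at offset —
are clinically meaningful markers of mobility, sedentariness and fall risk.
Wrist-worn devices struggle here because PD suppresses arm swing and adds
tremor; an ankle-worn inertial sensor is far less affected. `sitseg`
implements a complete pipeline that turns one ankle IMU stream (tri-axial
accelerometer in g, tri-axial gyroscope in deg/s, 50 Hz) into a list of Sit
phases with onset/offset times, and quantifies how well it does so.

The pipeline has five stages:

1. **Preprocessing.** Second-order zero-phase (forward–backward) Butterworth
   low-pass filters: 0.5 Hz on each acceleration axis (the slow,
   gravity-driven component that shifts when the shank changes posture) and
   4 Hz on each angular-velocity axis (voluntary movement incl. gait).
   Magnitudes are computed from the raw axes for the raw channels, and from
   the filtered axes for the filtered channels — each axis is filtered
   first, the magnitude taken second; the order matters and is tested.
2. **Features.** 1 s sliding windows with 90% overlap (50 samples advancing
   5 at 50 Hz). Per window, the mean and sample standard deviation of each
   of the 16 channels: 16 features from the raw signals, 16 from the
   filtered ones, 32 in all. Deliberately nothing more: amplitude and
   variability are what separates sitting from walking, and a larger
   feature set mainly buys overfitting risk.
3. **Normalization.** Each feature is mapped affinely by its 5th/95th
   percentiles, `(2v − (P5+P95))/(P95−P5)`, so P5 → −1 and P95 → +1, with
   no clipping beyond. Percentile bounds (rather than min/max) keep
   outliers from stretching the scale.
4. **Twin classifiers.** Two bagged random forests on the same 32 features:
   a *Transition* model (positives: stand-to-sit and sit-to-stand windows)
   with 35 trees and a *Sit* model (positives: seated windows) with 25
   trees. Ensemble sizes sit past the knee of the out-of-bag error curve
   (`oob_error_curve()` re-derives them on new data). Each training call
   fits 5 forests and keeps the one with the smallest OOB error.
5. **Merge.** Positive windows become detection intervals; then, in fixed
   order: (a) detections separated by less than 1.5 s are concatenated per
   track; (b) Transition detections outside a no-Walking segment are
   discarded; (c) Sit detections without a Transition detection in the same
   no-Walking segment are discarded; (d) surviving Sit detections in one
   no-Walking segment are concatenated, and the emitted Sit phase spans the
   earliest to the latest of them. No-Walking segments — the complement of
   detected walking — gate the whole merge: a sit phase necessarily begins
   and ends near transitions, and cannot occur while walking.

## Interval semantics and labeling

All intervals are half-open `[start, end)` in seconds, which makes abutment
and measure arithmetic unambiguous. Ground truth uses three labels (SIT,
TRANSITION, WALKING); anything else in a recording is background. A window
is labeled positive for a class when at least half of its span (inclusive)
lies inside an interval of that class — majority occupancy, the natural
rule when the underlying annotation does not dictate one.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window length | 1.0 | s | shortest span with a stable SD estimate; sub-second sits are declared undetectable |
| window overlap | 0.9 | — | 0.1 s hop bounds segmentation granularity |
| acc cutoff | 0.5 | Hz | isolates posture-driven gravity shifts |
| gyr cutoff | 4 | Hz | keeps gait, drops tremor-band energy |
| trees (Transition/Sit) | 35 / 25 | — | past the OOB-curve knee; cheaper training at equal error |
| training repeats | 5 | — | best-of-5 by OOB error |
| CV folds | 10 | — | grouped by subject (see below) |
| merge gap | 1.5 | s | empirically chosen bridging constant; exposed in `run_config()` |
| occupancy threshold | 0.5 | — | inclusive majority rule |

## Cross-validation and leakage

`crossvalidate()` groups folds by **subject** by default: windows 0.1 s
apart are near-duplicates, so a window-level split leaks heavily and
flatters every metric. Within each fold the normalization percentiles are
refit on the training windows only (the tests assert this structurally). A
window-level split (`grouping = "window"`) is kept as the permissive
alternative reading of a plain 90/10 segment split; it is not the default
and the two are not comparable. The percentile-normalization scope is
likewise a config switch: `"pooled"` (default) computes one P5/P95 per
feature over all subjects and trial lengths; `"per_subject"` normalizes
each subject by their own percentiles, which is self-contained and so needs
no refitting per fold.

One grouped cross-validation runs over the pooled cohort, and per-trial-
length results are aggregated from the held-out predictions (every trial is
predicted exactly once). Training one detector pair per fold on all trial
lengths pooled is the stricter leakage-safe design and keeps the number of
forest fits at `k × repeats × 2`.

## The synthetic cohort

No recorded cohort ships with the package, so `generate_cohort()` produces
one: by default 20 subjects × {3, 4, 5} min trials at 50 Hz, each trial
beginning seated and containing 3 seated phases separated by walking bouts
and brief standing, with per-subject gait frequency (0.8–1.2 Hz), gait
amplitude (80–160 deg/s), and activity durations drawn from configured
ranges. The signal model is deliberately minimal:

- the accelerometer reads the projection of 1 g under a shank tilt that
  ramps smoothly (cubic smoothstep) between its standing value (0°) and its
  seated value (40°, foot slid forward) over each 1.5–3 s transition;
- the gyroscope reads the tilt rate — a pulse during each transition — plus
  a sinusoid at the gait frequency during walking (dominant on the sagittal
  axis, weaker second harmonic elsewhere);
- optional 4–6 Hz tremor (off by default, on for robustness tests) and
  white noise (0.01 g, 0.5 deg/s) throughout.

A structural note on the activity script: since a trial begins with the
participant already seated, the first seated phase has no entry transition;
every seated phase is exited by a sit-to-stand, and phases after the first
are entered by a stand-to-sit. A script with `n` seated phases therefore
contains `n` sit-to-stand and `n − 1` stand-to-sit transitions — demanding
equal counts would contradict either the seated start or the requirement
that every stand-to-sit immediately precede a seated phase.

This generator captures exactly the phenomenology the pipeline's stages
consume — low-frequency acceleration plateaus that differ between postures,
gyroscope bursts at transitions, sustained gait oscillation — and nothing
else. What passing tests on it demonstrate is that the implementation is
correct and the pipeline recovers known ground truth under its own signal
model. It does **not** demonstrate performance on real PD data: real
signals add foot placement variability, orientation drift, non-sagittal
motion, dyskinesia, sensor re-mounting, and sit-down styles the tilt model
cannot produce. Published performance figures on patient cohorts are
therefore not reproduction targets here.

## Walking detection

The merge algorithm is gated by Walking/no-Walking segments that, in the
original design, come from a separately validated gait-detection algorithm
whose internals are out of scope here. `sitseg` offers two modes:
`"labels"` (default) passes externally provided Walking intervals through
verbatim — on synthetic data these are the generator's ground truth;
`"detector"` is a clearly flagged stand-in that thresholds the windowed
mean of the 4 Hz-filtered gyroscope magnitude (30 deg/s, minimum bout 2 s,
gaps bridged at 1.5 s). The stand-in is an energy detector, not a validated
gait algorithm, and logs itself as such.

## Numerical choices

- **Zero-phase filtering.** `signal::butter` coefficients; the
  forward–backward pass is applied with odd-reflection padding of
  `3 × (order + 1)` samples *and* steady-state initial conditions (the
  step-response fixed point of the filter state), so constants pass
  exactly and edge transients stay local. This matches the behavior of the
  standard `filtfilt` implementations in scientific Python/MATLAB.
- **Percentiles/quartiles.** Linear interpolation between order statistics
  (`stats::quantile` type 7) everywhere: normalization bounds, Tukey
  fences.
- **Standard deviation.** Sample (n−1) denominator.
- **Windows.** Start at sample 0; windows that would run past the signal
  end are dropped; a window's timestamp is its start time.
- **Gap rule.** Strictly less than 1.5 s merges; a gap of exactly 1.5 s
  does not.
- **Boundary assignment.** A detection straddling a Walking/no-Walking
  boundary belongs to the segment holding the majority of its duration
  (ties to the earlier segment); a Transition whose majority lies in
  Walking is discarded; Sit detections are clipped to no-Walking territory
  before the association rule, since emitted phases must live inside a
  no-Walking segment.
- **Vote ties.** A window is positive only when strictly more than half
  the trees vote positive (with odd tree counts, ties cannot occur).
- **Event matching.** Greedy one-to-one by descending temporal overlap
  (ties: earlier truth event, then earlier prediction); zero-overlap pairs
  never match. The matching rule is declared, since reported event counts
  depend on it.
- **ΔT.** Each matched event contributes two values, `|Δstart|` and
  `|Δend|`; per-event averaging is available as an option. Outliers use
  Tukey 1.5×IQR fences; the outlier percentage is the share of all ΔT
  values outside them — a declared definition.
- **Degenerate input.** Features with `P95 == P5` raise an error naming
  the feature; metric ratios with zero denominators report `NA` with a
  warning, never a silent 0.
- **Seeds.** One master seed; every stochastic step (script, synthesis,
  fold assignment, each training repeat, each OOB run) consumes a seed
  derived from it by a fixed integer-folding scheme, so whole runs are
  bit-reproducible.

## Validation problem sizes

The test suite validates operations against independent oracles (brute-force
window enumeration, quantile-by-sorting, an interval-algebra reimplementation
of the merge, the closed-form digital filter response, nearest-centroid and
permutation baselines for the forests). The end-to-end check runs the
default cohort — 20 subjects × 3 trial lengths, ~143k windows, 10-fold
subject-grouped CV — and requires event-level Sit sensitivity ≥ 0.90 and
median ΔT ≤ 1.0 s under low noise; the out-of-bag check traces error
against ensemble size on the 3-minute trials with 10 runs per count.
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Known limitations

- The generator's tilt model is 2-D (sagittal); device axes are treated as
  body-aligned, and no axis reorientation is attempted.
- The stand-in walking detector is intentionally naive; with poor walking
  segmentation the merge gate (rules b/c) dominates error.
- Sit events shorter than the 1 s window are undetectable by construction.
- Class imbalance is left as-is (no reweighting), matching the reference
  protocol; inverse-prevalence weighting would be a natural extension.
- The 1.5 s merge gap was chosen empirically for the original recordings;
  on other data it should be re-examined via `run_config(merge_gap_s = …)`.
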