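---
title: "Direction-dependent reaching kinematics: models, metrics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direction-dependent reaching kinematics: models, metrics and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachkin)
```

`reachkin` implements, as a tested pipeline, the analysis of a horizontal
center-out reaching study in poststroke hemiparesis: a synthetic cohort
generator that emulates an exoskeleton recording of the visually guided
reaching task, per-trial movement parameters for a movement-*quality*
analysis (movement time, path length, velocity peaks) and a
movement-*quantity* analysis (anteroposterior/mediolateral displacement),
and the group-level statistics (three-way repeated-measures ANOVA, linear
mixed model, paired t tests). This vignette is the package's account of
its modelling and numerical decisions.

## The task and its coordinate conventions

The task is a planar center-out reach: the hand cursor (0.4-cm radius) is
held inside a central target (1.0-cm radius) for a uniformly drawn
1,250–1,750 ms; a peripheral target (1.0-cm radius) then appears at 10 cm
in one of eight directions, and the participant has 3,000 ms to reach it.
A session has 64 trials scheduled so that every consecutive block of eight
trials contains each direction once. Recording is at 1 kHz with positions
quantized to 0.01 cm. All of this is encoded in `task_config()` and is the
configuration default.

Directions are labelled medial (M), medial-forward (MF), forward (F),
lateral-forward (LF), lateral (L), lateral-backward (LB), backward (B) and
medial-backward (MB). We work in a left-arm workspace frame with +x =
medial and +y = forward, with labels at exact multiples of 45°
counter-clockwise from M at +x. Only relative directions matter downstream,
so the choice of absolute frame is internal; right-arm recordings are
flipped onto this frame by negating x about the start position and
remapping M↔L, MF↔LF, MB↔LB (`mirror_to_left()`). The flip is an exact
involution, and every metric in the package is invariant under it (this is
property-tested).

Severity follows the Fugl-Meyer upper-extremity (FMA-UE) convention:
scores above 45 are *mild*, 30–45 *moderate*, below 30 *severe*;
analyses group moderate and severe together. `classify_severity()` treats
the score as an integer in 0–66 and rejects anything else rather than
rounding.

## The synthetic cohort generator

No recordings are distributed with the package; every analysis runs on
synthetic sessions with the statistical structure the downstream stages
assume. The generator is first-class, seeded code, not a test fixture.

**Reaches.** Completed reaches follow a minimum-jerk trajectory
(`minimum_jerk_reach()`), the canonical smooth-reach profile with a single
speed peak. Corrective submovements are modelled by
`add_submovements()` as a *chain* of minimum-jerk segments: one main
movement followed by `k` short corrections (~0.9 cm, ~170 ms), the last
correction deliberately larger (~3 cm, ~300 ms). Chaining makes speed
fall to near zero between segments, so the filtered profile shows exactly
`1 + k` positive peaks; the large final correction guarantees that target
entry (the movement-offset rule) falls *beyond* that correction's speed
maximum, keeping all `1 + k` peaks inside the onset–offset window. An
additive-bump construction was rejected: a Gaussian bump superimposed on a
slowly decaying carrier creates a second "recovery" maximum and breaks
the one-peak-per-submovement contract.

**Trial state machine.** `simulate_trial()` draws the hold duration, then
one of four outcomes: a hold failure (no target appears; probability
`hold_failure_prob`); a trial in which the hand never leaves the centre
(complement of `attempt_prob`); an *incomplete* trial in which the hand
leaves the centre but stalls; or a completed reach (probability
`completion_prob_by_direction`, given an attempt). Reaction latency is
uniform 200–400 ms; reach durations scale by `time_scale_by_direction`,
which is ≥ 1 and largest for anteroposterior directions — the generator's
encoding of the direction-dependent performance differences the analysis
is designed to detect.

**Incomplete movers.** Incomplete trials are bouts of out-and-back
minimum-jerk excursions (2.2–5 cm) separated by pauses, with each bout's
axis drawn mediolateral with a probability calibrated so that the
*measured* pooled L1 mediolateral share equals the profile's `ml_bias`.
The calibration corrects in closed form for the ±3° angular jitter of the
bouts and for the symmetric L1 displacement contributed by quantized
positional noise; the noise term uses the realized total variation of the
trial's own noise series, an axis-exposure model (noise on an axis is
absorbed while that axis moves fast), and an empirical attenuation
constant κ = 0.75 for the part of the noise total variation that
quantization absorbs once the noise rides on a moving excursion. With
this calibration the injected `ml_bias` is recovered by
`participant_ml_proportion()` to within about one percentage point in the
mean at a few hundred trials (property-tested at ±3 points).

**Noise and quantization.** Hold-phase and trial-wide positional jitter is
white noise low-passed at 5 Hz and rescaled to `noise_sd` (default
0.04–0.08 cm by severity), so pre-illumination speeds are nonzero and the
onset thresholds nondegenerate. All coordinates are then quantized to
0.01 cm. A consequence worth knowing: at 1 kHz a 0.01-cm quantum
corresponds to 5 cm/s speed steps, so the pooled *median* pre-illumination
speed is typically zero and the lower onset threshold with it — the
upper-threshold/local-minimum branch of the onset detector is the
operative criterion on realistic data, and on exactly noiseless data the
onset detector falls back to the illumination time (see below).

**Joint angles.** Shoulder/elbow angles come from planar two-link inverse
kinematics (`joint_angles_from_hand()`), elbow-down branch, with link
lengths L1 = 30 cm (upper arm) and L2 = 33 cm (forearm to fingertip) —
adult-scale defaults; only joint-angle outputs depend on them. The
shoulder position is *constructed* so that the hand at the central target
gives exactly 30° shoulder horizontal adduction and 90° elbow flexion,
the task's start posture. Conventions: adduction positive toward the
midline, flexion positive, 0° elbow = full extension. The
forward/inverse round trip reproduces hand positions to < 1e-9 cm.

**Cohort structure.** `cohort_spec()` defaults encode the study
conditions: 13 mild and 15 moderate-to-severe participants; admission
FMA-UE drawn from N(59.0, 5.7²) clipped to 46–66 (mild) and N(19.4,
14.4²) clipped to 3–45 (moderate-to-severe); a non-negative improvement
at discharge (N(3.3, 4.8²) and N(9.5, 6.75²), truncated at zero so
discharge is never worse — which makes the simulated paired t statistics
slightly larger than untruncated sampling would); and mediolateral energy
shares for incomplete movement of 0.686 → 0.617 (more-affected side,
admission → discharge) and 0.531 → 0.523 (less-affected), with persistent
between-participant jitter (SD 0.055 and 0.018). The more-affected arm's
attempt and completion probabilities are logistic in the FMA-UE score,
calibrated so mean exclusion rates land near the clinically reported
ranges (about 10% quality-arm exclusions in the mild group, about 65% →
45% quantity-arm exclusions in the moderate-to-severe group). One cohort
seed expands to per-session seeds as `seed * 1000 + session_index`, so any
single session is reproducible in isolation.

**What the generator does not emulate.** No muscle activity, torques or
interaction dynamics; no trunk compensation (the task straps the trunk);
no within-session fatigue or learning; the severity-to-kinematics mapping
is a calibration device, not an estimate of any cohort. Passing the
recovery tests therefore shows that the *pipeline* measures what the
generator injects — it does not validate the generator against real
patients. Two visible consequences: simulated covariance across the eight
directions is close to spherical, so Mauchly's test rarely triggers the
Greenhouse–Geisser correction that real data regularly need; and the
less-affected side's mediolateral share sits near 50–51% (geometry of
complete reaches) rather than the reported ~53%.

## Per-trial movement parameters

**Speed** is the magnitude of the central-difference velocity of the
quantized positions (forward/backward differences at the ends).

**Thresholds.** The lower/upper speed thresholds are the median and 95th
percentile (linear interpolation between closest ranks, `type = 7`) of
the pooled per-millisecond speeds from the 500-ms windows before each
target illumination, across all trials of a session in which a target
appeared. Pooling all samples is the default reading of "median across
all trials"; a median-of-per-trial-medians variant is available
(`method = "per_trial_median"`).

**Onset** (`detect_onset()`): find the first post-illumination sample at
which the hand leaves the central target, then scan *backward* toward
illumination and return the first sample that is either a strict local
minimum of unfiltered speed below the upper threshold, or a sample with
speed strictly below the lower threshold. If the scan exhausts, the
illumination time is returned and flagged. "Leaves the central target"
defaults to the cursor centre exceeding `central_radius + cursor_radius`
(1.4 cm) from the start; `containment_exit` (0.6 cm) and `center_exit`
(1.0 cm) are available by configuration, because display semantics of
"within the target" can be read either way.

On *exactly noiseless* data both thresholds degenerate to zero and the
strict inequalities never fire, so onset falls back to illumination; the
peak-count window then includes a long identically-zero span where the
zero-phase filter's tiny ringing creates spurious strict local maxima.
This is a degenerate corner, not a property of realistic data; the
package's smoothness tests on noiseless traces therefore apply
device-floor thresholds (0.5 and 2.0 cm/s) — the same construction used
to specify the onset rule — under which the window starts at the true
movement start and a clean reach counts exactly one peak.

**Offset** is the first post-illumination sample at which the cursor is
inside the peripheral target; the default entry rule is the cursor centre
within the target circle (≤ 1.0 cm), with a circle-overlap variant
(≤ 1.4 cm) by configuration.

**Movement time** is offset − onset; **path length** is the summed
Euclidean norms of successive displacements over that window.

**Velocity peaks.** Hand speed is filtered with a zero-phase Butterworth
low-pass at 10 Hz: an order-3 design applied forward and backward, whose
squared magnitude response is the stated sixth-order characteristic (at
50 Hz the response is below 10⁻⁴; a 1-Hz component is preserved within
1%). The implementation de-means the series (exact unit DC gain) and
pads by odd reflection so the forward–backward transients stay in the
pads. Peaks are interior samples strictly greater than both neighbours —
no amplitude or spacing thresholds, plateaus are not extrema, window
endpoints are never peaks.

**Displacement decomposition.** AP_total = Σ|y_{t+1} − y_t| and
ML_total = Σ|x_{t+1} − x_t| over the span from target illumination to the
end of the outbound reach phase (target entry, the 3,000-ms limit, or the
end of the recorded excursion). The outbound-only span is a deliberate
choice — the return to centre is a different behaviour — and a
whole-recording span is available by argument. The per-participant
mediolateral proportion pools AP and ML over all qualified trials first
and then forms 100·ML/(AP+ML); a participant with no qualified trial
yields `NA` and is recorded as missing rather than imputed.

**Joint-path normalization.** Per trial, shoulder/elbow angles relative
to the onset posture are linearly resampled onto a fixed 0–100% grid
(101 points), first point exactly (0, 0), so trials of different duration
are comparable.

## Trial qualification

The *quality* arm keeps trials in which a target appeared, the target was
reached, and the reach took ≤ 3,000 ms. The *quantity* arm keeps trials
in which a target appeared and the hand left the centre, regardless of
success — so the quality-included set is always a subset of the
quantity-included set. Hold-failure (no-target) trials count in the
denominator of exclusion percentages, matching the device's behaviour of
incrementing the trial counter without a target; this is configurable in
principle but fixed here as the documented reading.

## Group-level inference

**Repeated-measures ANOVA.** `rm_anova_3way()` runs the full
within-subject decomposition (direction × side × time, all within) on the
per-cell means of one quality metric, through a multivariate linear model
and `car::Anova` — the standard R route. Per multi-level effect,
Mauchly's test is computed from the orthonormal-contrast covariance; the
Greenhouse–Geisser correction (df multiplied by ε, with 1/(k−1) ≤ ε ≤ 1
and ε = 1 for two-level effects) is applied *only* when Mauchly's P is
below α = 0.05. A sum-of-squares conservation identity (total SS =
subject SS + Σ effect SS + Σ error SS) is verified to 1e-8 on every call,
and the full decomposition is tested against an independent
inclusion-exclusion cell-means oracle. One property worth stating
precisely: the folklore claim "ε-corrected P ≥ uncorrected P" is
guaranteed only where the correction can matter (large F); for F near or
below 1 the df shrinkage can slightly *reduce* the upper-tail
probability, which never changes a conclusion. The tests assert the
ordering in the significance region.

**Mixed model.** `fit_lmm_proportion()` fits
`ml_pct ~ side * time + (1 | participant)` by REML with sum contrasts,
reporting type-III F tests with Satterthwaite denominator degrees of
freedom (`lmerTest`) — fractional dfs of the kind SPSS prints. The model
absorbs missing participant × timepoint cells without dropping whole
participants; participants rejected from the quality arm are not imputed.
With zero between-participant variance the fixed estimates coincide with
ordinary least squares (tested to 1e-6); degenerate (constant) responses
are rejected as singular.

**Paired t.** Classical paired t on discharge − admission FMA-UE scores,
df = n − 1, two-sided, per group. No multiplicity adjustment is applied
across the three quality metrics, matching the analysis being emulated.

## Numerical choices and degenerate inputs

* Percentile convention: linear interpolation between closest ranks;
  configurable since no convention is stated for the thresholds.
* Strict inequalities everywhere extrema are involved (onset local
  minima, velocity peaks); plateaus are never extrema.
* Quantized coordinates are snapped back onto the 0.01-cm grid when
  sessions are reloaded from CSV, so a written-and-read session is
  bit-identical to the in-memory one.
* Unreachable hand positions are rejected by the inverse kinematics with
  the offending trial and sample named; never-entering trials are
  rejected by `detect_offset()` (the qualifier should have excluded
  them); series shorter than 24 samples are rejected by the filter.
* All simulation randomness flows through explicit seeds; a cohort, a
  session, or a single trial stream can be reproduced in isolation.

## Problem sizes used by the test-suite

The suites run at the task's own constants (64-trial sessions, 1 kHz).
Oracle-equivalence sweeps use 1,000 random trials/series; the null
calibration of the ANOVA engine uses 500 replicates of a 13-participant
table (observed type-I rate within ±0.02 of 0.05); the power check of the
mixed model uses 50 replicates at n = 15 with a 5-point side × time
interaction and the module's default variance components (participant SD
3, residual SD 3); the end-to-end signature check uses 50 cohort
replicates of 8 mild participants × 24-trial sessions, restricted — as
the group definition itself does — to participants with complete
direction × side × time cells. These sizes are the package's choice of a
desk-scale experiment; effect sizes and generator defaults are the study
conditions throughout.

## Known limitations

The generator's phenomenology is kinematic only, and its parameters are
not fitted to any real cohort; absolute agreement with published group
statistics is out of reach by design (the underlying recordings are not
deposited) and is not asserted anywhere. The ANOVA engine requires a
complete within-subject design, as the quality arm guarantees for the
mild group; unbalanced quality designs are rejected, not approximated.
Sphericity violations are rare in the synthetic covariance, so the
Greenhouse–Geisser path is exercised mainly by dedicated tests rather
than by default cohorts.
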