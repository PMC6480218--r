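---
title: "Feature-based TUG sub-task segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based TUG sub-task segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
the design is the way it is. The worked numbers it mentions are the ones
the test suite and `scripts/acceptance.R` compute; nothing here is
asserted that the code does not measure.

## The measurement problem

A 3-m Timed Up & Go trial recorded by a single IMU at L3–L4 yields, after
onboard sensor fusion, trunk orientation angles at 100 Hz: pitch
(sagittal inclination, forward lean positive) and yaw (transverse-plane
heading), plus raw accelerometer and gyroscope channels. The six
sub-tasks leave distinct signatures:

* stand-up and sit-down each produce a forward-lean *bump* in pitch of
  roughly 2–11 degrees;
* each of the two turns is a smooth ≈180-degree transition in yaw
  between flat heading plateaus;
* steps appear as oscillations of the vertical acceleration at the
  gait cadence.

The segmentation is deliberately *feature-based* — fixed signal-shape
criteria, no training data — so it stays auditable and runs anywhere.

## Signal conditioning

Both angle channels pass through the same pipeline before detection:

1. **Zero-referencing.** The median of the first 0.5 s
   (`baseline_window`) is subtracted. This step matters: a constant
   mounting offset (say a 15° resting pitch) would otherwise dominate
   the absolute-maximum normalisation and crush the stand/sit bumps the
   slope criterion thresholds at 0.05.
2. **Yaw only: unwrapping and orientation.** Heading wraps at ±180°;
   360° multiples are added wherever a successive difference exceeds
   180° in magnitude (valid at 100 Hz, where true per-sample rotation is
   far below 180°). The signal is then mirrored if its largest excursion
   is negative, so the first turn is always a positive rotation — the
   detector's order convention. The subject's true turn direction is
   kept as metadata.
3. **Smoothing.** A causal-forward moving average of order `N = 5`,
   `y[n] = mean(x[n..n+N-1])`; the last `N − 1` samples use a shrinking
   tail window so output length equals input length and indices map 1:1
   onto raw samples (an alternative would truncate the signal and shift
   every downstream index).
4. **Normalisation** by the absolute maximum, recording the scale in
   degrees. An identically zero signal is passed through with a
   degenerate flag rather than dividing by zero.

The yaw processing order — unwrap → zero-reference → orient → smooth →
normalise — is fixed because each later step assumes the earlier one's
contract (e.g. orientation inspects the zero-referenced excursion, not
the raw heading).

## Posture-transition detection

The two most *prominent* local maxima of conditioned pitch separated by
at least `peak_min_separation = 3` s are the stand and sit peaks.
Prominence rather than raw height rejects gait oscillations; 3 s is far
below any plausible stand→sit gap yet above bump width. Around each peak
the bounds come from the slope-stop search: step outward in strides of
`slope_stride = 0.1` s and stop the first time the lagged difference
`|x(t ∓ i ∓ 0.1) − x(t ∓ i)|` falls below
`slope_stop_threshold = 0.05`. The iterator is read in *seconds*
advancing in 0.1-s steps (a 10-sample stride at 100 Hz); reading it in
sample units would change the stride a hundredfold and contradict the
units of the peak-time arithmetic. Bound times are snapped to the sample
grid, since all downstream arithmetic is sample-indexed.

Two documented edge behaviours: a search that reaches the recording edge
clamps there with a flag (not an error), and a transition so shallow
that the lagged difference never exceeds the threshold *collapses onto
the peak* — the criterion fires at `i = 0`. The collapse case is the
method's intrinsic fragility, discussed under limitations.

## Turn detection

On the oriented signal the 3-m turn is the rising heading transition and
the pre-sitting turn the falling one, so the global maximum and minimum
of the derivative (central difference × fs) locate them; the maximum
must precede the minimum. A `turn_window = 10`-sample window then slides
one sample per step away from each extremum: for the 3-m turn, leftward
while the window mean exceeds `turn_low_level = 0.02` (the bound is the
final window's left edge) and rightward while the mean is below
`turn_high_level = 0.9`; for the pre-sitting turn the criteria mirror.
The rotation span over the detected interval, measured on the unwrapped
degree-valued signal, should be ≈180°; spans outside (90°, 270°) set a
warning flag rather than failing, since hard-failing would reject valid
pathological gait.

The literal scheme assumes the turns rotate in opposite directions. Some
subjects turn the same way twice (heading 0° → 180° → 360°); for them
`robust_turns = TRUE` switches to a generalisation that takes the two
largest-magnitude disjoint rate excursions of either sign, estimates
each turn's flanking heading plateaus from the quiet stretches around
it, and applies the same 0.02/0.9 criteria on a locally rescaled copy of
the signal. Robust mode also tolerates incomplete turns whose plateaus
are not at 0/1 of the global normalisation — the literal mode's level
criteria inherit that fragility by construction, and a plateau that
never reaches 0.9 sends the literal search to the recording edge
(clamped and flagged).

## Assembly, features, risk

The first walk is `[standing end, turn1 start]` and the second
`[turn1 end, turn2 start]`. The interval between the pre-sitting turn's
end and the sitting start is kept as an explicit labelled gap ("pre-sit
stance") rather than forced to zero, preserving both detectors' outputs;
the total time runs standing start → sitting end regardless. Boundary
inversions up to 0.2 s — expected, since four independent detectors
bound adjacent intervals — are resolved at the midpoint with a flag;
larger inversions are a consistency error naming the conflicting events.

Features per sub-task: peak median-detrended vertical acceleration
during standing/sitting; peak transverse rotation rate per turn (the
gyroscope channel when present, otherwise the differentiated unwrapped
yaw, flagged `turn_rate_derived_from_yaw`); step counts from local
maxima of the detrended vertical acceleration with prominence ≥
`step_min_prominence = 1` m/s² and separation ≥
`step_min_distance = 0.3` s (the median is a robust gravity estimate
over short segments); and trunk-inclination excursion from the
recording's baseline posture. Features whose source channel is missing
are reported absent (`NA`), never zero.

Risk classification is a step function of total time against two
strictly increasing cutoffs, default 10 s and 20 s (no / low / high).
The cutoffs are deliberately configuration, not constants: the reference
older-adult table contains a 9.33-s trial labelled low risk, so the
issuing authority's bands are evidently not a pure 10-s rule (likely
age-adjusted), and the package therefore never hard-codes them into
validation — concordance is computed on the labels as printed.

## The synthetic trial generator

`simulate_tug()` builds recordings whose morphology matches what the
lumbar sensor sees, with exact ground truth:

* **Pitch: sharp-peaked triangular bumps** spanning exactly the
  standing/sitting intervals. Real sit-to-stand inclination rises and
  falls briskly around a sharp peak. A flat-topped bump (e.g. a raised
  cosine) of duration D has a lagged difference near its peak of about
  `A·π²·0.01/D²`, which falls below the 0.05 slope-stop threshold for
  D ≳ 1.4 s — at typical sitting durations the bound search would
  collapse onto the peak by construction, which is neither what real
  signals do nor a useful test bed. The triangle's constant flank slope
  `2A/D` keeps the criterion meaningful at all realistic durations.
* **Yaw: cubic smoothstep transitions** spanning exactly the turn
  intervals. Finite support makes true start/end well defined for error
  scoring (a logistic would only approach its plateaus asymptotically),
  and zero end-slope means the window criteria fire strictly inside the
  true interval. With a smoothstep the peak turn rate is analytically
  `1.5·turn_angle/duration`, so requesting a `peak_turn_rate` sets the
  turn durations rather than adding an inconsistent free parameter.
* **Vertical acceleration**: gravity, plus one sinusoidal cycle per
  step during walks and turns (step count = cadence × duration,
  rounded), plus raised-cosine transients at stand/sit, plus white
  noise.
* **Gyroscope channels**: analytic derivatives of the noiseless
  orientation signals plus white noise.
* **Orientation noise is band-limited, not white.** The error of a
  Kalman-fused orientation estimate is dominated by slowly varying
  components (attitude drift, magnetic disturbance); 100-Hz white angle
  noise would make the 0.1-s lagged-difference statistic noisier than
  the 0.05 threshold itself at sub-degree amplitudes and is physically
  wrong for a fused output. The generator uses a stationary AR(1)
  process with a 2-s correlation time and SD `noise_sd_angle = 0.3°`
  (sub-degree residual error, consistent with a ±1° accuracy rating);
  inertial channels keep genuine wideband noise (0.4 m/s², 2 deg/s).

`random_scenario()` draws sub-task durations from truncated normal
distributions with the validation groups' video-timing means and SDs
(young: 1.16 ± 0.15 s standing through 1.48 ± 0.17 s sitting; older:
wider and slower), and amplitudes/cadence from the per-group feature
distributions truncated to their observed ranges; truncation at ±2 SD
(with a 0.4-s floor) keeps draws physiologic. The two pitch amplitudes
are drawn independently from their marginals.

What the generator does *not* emulate: double support and arm swing,
pitch oscillation during gait, gyro bias drift, pauses or aborted
attempts, and within-subject correlation between stand and sit
amplitudes. Passing closure tests therefore show the detectors recover
the stated morphologies under realistic noise — not that every
pathological real-world trial will segment cleanly.

## Problem sizes and numerical choices

The closure benchmark used by the tests and the acceptance script runs
100 random young-population trials (~13 s of signal each at 100 Hz)
through the full pipeline, a few seconds of compute in total. Ties in
the peak search resolve to the earlier sample; between-sample times snap
to the nearest sample; all intervals are closed; report times are
written with 3 decimals, which is lossless for sample-aligned events at
100 Hz and makes repeated runs byte-identical. Every simulation helper
takes an explicit seed and restores the caller's RNG state.

## Known limitations

* **Shallow-bump collapse.** When the stand and sit bump amplitudes
  differ by more than about a factor of two, the smaller bump —
  normalised by the *global* maximum — can present a flank slope below
  0.5 normalised units/s, and the 0.05 slope-stop criterion then fires
  early or at the peak. In the closure benchmark this affects roughly
  1% of boundaries (errors up to ~0.8 s) and is the dominant error
  mode; it is a property of the fixed-threshold method itself, visible
  in the benchmark because the generator draws the two amplitudes
  independently.
* **Systematic turn-end offset.** The 0.9 window-mean criterion fires
  where the transition passes 90% of its amplitude — for any smooth
  monotone transition completing at the interval end, about
  0.2 × duration before that end (cubic smoothstep: at 80.4% of the
  interval). The 3-m turn's end and, mirrored, the pre-sitting turn's
  start therefore carry a systematic early bias of ~0.2–0.35 s that no
  amount of noise reduction removes.
* The literal turn detector requires opposite-direction turns; robust
  mode is explicit opt-in, and both modes are reported in the output.
* The agreement statistics on the packaged reference tables are
  computed from times printed to two decimals; the young-group
  correlation computed from those printed values is 0.977.
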