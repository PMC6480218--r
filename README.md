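# tugseg

Sub-task segmentation and mobility analysis of the 3-m Timed Up & Go
(TUG) test from a single lumbar-mounted IMU.

The TUG test — rise from a chair, walk 3 m, turn, walk back, sit down —
is the standard clinical screen for fall risk in older adults, but its
single stopwatch time hides *where* a patient struggles. With one
inertial sensor worn at L3–L4, the trunk's orientation signals carry
enough structure to split the test into its six sub-tasks automatically:
**standing**, **first walk**, **3-m turn**, **second walk**,
**pre-sitting turn** and **sitting**. `tugseg` implements that
feature-based segmentation, extracts per-sub-task mobility features, and
classifies fall risk from the total time.

## Method

Two orientation channels drive the segmentation, each smoothed by a
forward moving average of order *N* = 5 and normalised by its absolute
maximum after zero-referencing against the initial posture:

* **Posture transitions (pitch).** Standing up and sitting down produce
  a forward-lean bump in the sagittal inclination. The two most
  prominent maxima of the conditioned pitch, `Tpeak1` and `Tpeak2`, mark
  the stand and sit events; each event's bounds are found by walking
  outward from the peak in 0.1-s strides until the lagged difference
  `|pitch(t ± i ± 0.1) − pitch(t ± i)|` drops below 0.05 — the "slope
  stop" criterion.
* **Turns (yaw).** Each ≈180° turn is a smooth transition in the
  (unwrapped, orientation-normalised) heading. The global maximum and
  minimum of `d(yaw)/dt` locate the 3-m and pre-sitting turns; a 10-sample
  sliding window then finds each turn's bounds from window-mean level
  criteria at 0.02 (pre-turn plateau) and 0.9 (post-turn plateau).

The walks fill the space between those four events. From the segments,
the package extracts durations, peak vertical accelerations at stand/sit
(Acc. Su/Sd), peak turn rates (Vel. T1/T2), step counts per segment
(peak detection on detrended vertical acceleration), and trunk
inclination excursions (Pitch Su/Sd). Total time (standing start →
sitting end) feeds a configurable two-cutoff risk classifier
(defaults 10 s / 20 s: no / low / high risk).

A synthetic trial generator (`simulate_tug()`, `random_scenario()`)
produces population-typical recordings with exact ground-truth event
times, so the whole pipeline is testable end to end, and a validation
module supplies Pearson correlation, Bland–Altman limits of agreement
and risk-category concordance, together with packaged per-subject
reference timing tables for two validation groups (25 young adults,
12 older adults).

## Worked example

```r
library(tugseg)

sim <- simulate_tug(tug_scenario(seed = 42))   # a typical young-adult trial
res <- run_pipeline(sim$recording)
res$segmentation
#> TUG segmentation
#>   standing     [  1.45,   2.65] s  (1.20 s)
#>   first_walk   [  2.65,   5.22] s  (2.57 s)
#>   turn_3m      [  5.22,   6.53] s  (1.31 s)
#>   second_walk  [  6.53,   9.33] s  (2.80 s)
#>   presit_turn  [  9.33,  10.18] s  (0.85 s)
#>   sitting      [ 10.18,  11.66] s  (1.48 s)
#>   total time   10.21 s
res$risk
#> Fall risk: low (total time 10.21 s; cutoffs 10 / 20 s)
```

The features report five steps in the first walk, six in the second, a
peak 3-m turn rate of 167.6 deg/s and a 4.9° standing trunk lean — and
against the generator's exact ground truth every segment boundary here
is recovered to within 0.29 s. A JSON report of everything, including
the resolved configuration, comes from
`write_report(res$segmentation, res$features, res$risk, "report.json")`.

The same pipeline runs from a shell on delimited sensor exports (time,
pitch/yaw or quaternions, optional inertial channels):

```sh
inst/scripts/tugseg run rec.csv --out report.json --annotate samples.csv
inst/scripts/tugseg simulate --population older --seed 9 --out rec.csv
```

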