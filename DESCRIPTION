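Package: tugseg
Title: Sub-Task Segmentation and Mobility Analysis of the 3-m Timed Up & Go
    Test from a Single Lumbar IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a 3-m Timed Up & Go (TUG) recording from a single
    lumbar-mounted inertial measurement unit into its six sub-tasks
    (standing, first walk, 3-m turn, second walk, pre-sitting turn,
    sitting) using a feature-based algorithm on the trunk pitch and yaw
    orientation signals. Detects sit-to-stand and stand-to-sit events from
    smoothed, normalised pitch via a slope-stop search around the
    inclination peaks, and the two 180-degree turns from the yaw
    derivative via sliding-window level criteria. Extracts per-sub-task
    mobility features (durations, peak vertical accelerations, peak turn
    rates, step counts, trunk inclinations), classifies fall risk from
    total test time against configurable thresholds, and provides
    method-agreement statistics (Pearson correlation, Bland-Altman limits
    of agreement, risk-category concordance) together with a synthetic
    recording generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
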