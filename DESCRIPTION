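Package: kneestab
Title: Wearable-Sensor Assessment of Knee Stability and Its Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for magneto-inertial (MIMU) and force-plate assessment of
    knee stability during single leg squat (SLS), crossover hop (CHT) and
    countermovement jump (CMJ) tests. Covers gyroscope bias removal,
    quaternion complementary-filter orientation estimation, automatic task
    segmentation (squat phases, hop take-off/landing via angular-velocity and
    jerk thresholds, jump unweighting and flight onset), extraction of
    temporal, acceleration- and angular-velocity-based stability parameters
    (including 90% prediction-ellipse sway metrics), and test-retest
    reliability statistics: absolute-agreement two-way mixed ICC with 95%
    confidence intervals, SEM, minimum detectable change, limb symmetry index
    and ICC-based sample-size planning. A synthetic-signal module generates
    physiologically shaped recordings with known ground-truth events and
    variance components so that every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    zoo,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
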