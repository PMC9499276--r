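---
title: "Assessing knee stability from wearable sensors: models, detectors and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing knee stability from wearable sensors: models, detectors and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneestab)
```

## The problem

After anterior cruciate ligament (ACL) reconstruction, clearance to return
to sport hinges on functional tests -- single leg squats, hop tests, jumps --
that are usually scored only by their gross outcome (distance hopped, time
taken). Magneto-inertial measurement units (MIMUs) strapped to the tibia and
the foot dorsum can instead quantify *how* the task is executed: how fast
the segments rotate and accelerate in the 100 ms after landing when ACL
injuries occur, and how much the tibia wanders in its transverse plane
during a squat. For any such parameter to be clinically useful its
test-retest reliability must be known; a change smaller than the
measurement's minimum detectable change (MDC) means nothing.

`kneestab` implements the full chain: raw tri-axial streams to orientation,
orientation to task events, events to stability parameters, parameters to
reliability statistics (ICC, SEM, MDC, limb symmetry index, sample-size
planning). Because raw athlete recordings of this protocol are not publicly
deposited, the package ships a synthetic-signal module that generates
physiologically shaped recordings with known ground truth, so every stage is
verifiable end to end.

## Sensor model and orientation estimation

Recordings are tri-axial accelerometer (±16 g), gyroscope (±2000 °/s) and
magnetometer (±4800 µT) streams at 500 Hz, with the sensor x-axis along the
segment's longitudinal axis; vertical ground-reaction force (GRF) comes from
a 1000 Hz force plate. The constant gyroscope bias is measured over an
initial still window (default 1000 samples) and subtracted
(`remove_gyro_bias()`).

`estimate_orientation()` is a quaternion error-state complementary filter.
The body-to-world quaternion is propagated by exact gyroscope integration
(axis-angle exponential per sample) and corrected with proportional
feedback:

* the gravity-direction error -- cross product of the normalized
  accelerometer reading with the predicted vertical -- weighted by
  `k1 = 2.33` (1/s);
* the heading error from the magnetometer, weighted by `k2 = 7.44` (1/s).

Three choices deserve comment:

* **Gains as 1/s feedback rates.** `k1` and `k2` act as first-order feedback
  gains, giving an accelerometer-correction time constant of `1/k1 ≈ 0.43 s`.
  The alternative reading (dimensionless blend weights) is not adopted; the
  static-convergence test (an injected 10° initialisation error must decay
  within `5/k1` seconds) pins down the implemented semantics.
* **Heading-only magnetometer correction.** The magnetometer error vector is
  projected onto the estimated vertical before being applied. A full-vector
  correction at `k2 = 7.44` would let magnetometer noise leak into the pitch
  angle, inflating exactly the signal the squat segmentation thresholds; the
  projection (standard practice in Mahony-style filters) keeps inclination
  referenced to gravity alone.
* **TRIAD initialisation.** The initial orientation and the world-frame
  magnetic reference are built from the accelerometer/magnetometer means of
  the first still second, so there is no gyroscope drift at `t = 0`.
  Initialisation aborts if the mean accelerometer norm deviates more than
  50% from g.

The tibia pitch angle (`tibia_pitch()`) is the rotation about the sensor Y
axis relative to the initial posture, reported in degrees with knee flexion
positive (a `flip` flag accommodates inverted mounting). `global_acc` is the
body-frame acceleration rotated into a vertically aligned inertial frame;
rotation preserves norms, and over still intervals it averages to
`(0, 0, g)` -- both are tested invariants.

## Task segmentation

**Single leg squat (SLS).** A 10-sample moving standard deviation σ of the
pitch angle, multiplied by ten, is compared against `2·σ_static`, where
`σ_static` is the SD of the first 1000 samples of quiet stance. The squat
start is the first instant the scaled σ exceeds the threshold; the eccentric
phase ends at the pitch maximum; the squat ends when the angle first returns
to its start value. Implementation decisions:

* The ×10 factor is applied to the moving SD only (the comparison is
  `10·σ > 2·σ_static`, i.e. an effective sensitivity of `σ_static/5`). The
  alternative, presentation-only reading (both sides scaled) is available
  via `scale_both_sides = TRUE`, but raises the detection latency to the
  time the pitch *slope* needs to move the 20 ms window SD past
  `2·σ_static` -- several tens of milliseconds into the descent for any
  realistic squat speed.
* The return-to-start tolerance band defaults to the same sensitivity as
  the start rule (`σ_static/5`); a `2·σ_static` band would flag the end
  10--20 ms early on the flattening return curve. `return_band` overrides.
* A candidate start must keep σ above threshold for `min_run_s = 0.05 s`
  (the reported onset is the beginning of the run, so latency is
  unaffected). Sensor-noise excursions over a 20 ms window occasionally
  cross a threshold as small as `σ_static/5`; a squat keeps it crossed.
  The search also begins only after the static reference window.

**Crossover hop test (CHT).** Take-offs are detected where the time
derivative of the foot angular-velocity magnitude first falls below
−0.6 rad/s²; each landing is the first local maximum of the derivative of
the acceleration magnitude exceeding 7 m/s³ after the take-off; a 100 ms
risk window `t_risk` follows each landing. Both magnitudes are smoothed with
a centred 80 ms moving average before differencing: raw central differences
of 500 Hz accelerometer noise have a jerk SD near 70 m/s³, which would bury
a 7 m/s³ threshold; after smoothing the noise floor sits near 0.6 m/s³. The
smoothing width matches the ~40 ms rise of impact loading, so the smoothed
jerk peak stays on the true landing instant. Events alternate under a 200 ms
refractory period -- shorter than any plausible flight or contact time, long
enough to skip the threshold crossings produced by the landing burst's
decay. Detection operates on frame-invariant signal magnitudes, so no
orientation estimate is required.

**Countermovement jump (CMJ).** Body weight is the mean GRF over the first
0.5 s of quiet standing. The end of the unweighting phase is the first
inflection (zero crossing of the second derivative) of the smoothed GRF
after the force drops 20 N below body weight; flight starts at the first
sample at or below 5 N -- force plates carry a noise floor, so "zero" is a
configurable threshold. The GRF is smoothed with a centred 40 ms moving
average and the second derivative uses a 40 ms stencil; narrower stencils
amplify plate noise quadratically in the sampling rate.

## Stability parameters

All RMS and peak parameters operate on the vector magnitude of the
tri-axial signal (reports carry one value per sensor, not per axis), in
m/s² for accelerations and °/s for angular rates (internally rad/s; the
conversion is an exact `180/π` round trip). For the SLS every parameter is
computed on the eccentric phase only; tibia RMS accelerations are
gravity-removed in the vertically aligned frame. For the CHT only the
second hop is used -- take-off technique of the first hop and landing
technique of the third are too variable -- and all RMS/peak parameters are
evaluated inside the 100 ms risk window after the second landing on raw
body-frame magnitudes. `FT = LA_i − TO_{i−1}` and `CT = TO_i − LA_{i−1}`
follow the hop indexing applied to the second hop; the total duration runs
from first take-off to last landing.

The transverse-plane sway of the tibia is summarised by the path length
(`sway_path()`) of the y-z acceleration trajectory, the area of its 90%
prediction ellipse and that ellipse's eccentricity
`SAecc = sqrt(1 − b²/a²)`. The ellipse semi-axes are `sqrt(q·λ_i)` with
`λ_i` the sample-covariance eigenvalues; the coverage quantile `q` defaults
to the small-sample form `2(N−1)/(N−2)·F_0.90(2, N−2)`, which converges to
the χ²₂ quantile 4.605 as N grows (`method = "chisq"` selects the
large-sample form directly). Sway area is reported in m²/s⁴ -- the area of
a region in an acceleration plane. For the CMJ, `F_max` is the maximum
*net* vertical force (GRF minus body weight) over the segmented window --
the net convention is the only one consistent with per-limb maxima of a
few hundred newtons -- and `AUC_F` is the trapezoidal integral of net force
over the window divided by body mass, i.e. the take-off velocity under the
impulse-momentum theorem.

## Reliability statistics

`icc_absolute_agreement()` computes the single-measurement,
absolute-agreement intraclass correlation from the two-way
subjects-by-trials ANOVA decomposition,

$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the 95% confidence interval and p-value from the McGraw--Wong
F-distribution formulas. The single-measurement form is the default because
SEM and MDC describe the error of one measurement; the average-measurement
form is exposed via `type = "average"`. `SEM = SD·sqrt(1 − ICC)` and
`MDC = SEM·1.96·sqrt(2)`. The SD entering the SEM is the SD of all `n·k`
trial values, not the SD of per-subject medians: a between-subject SD would
make the MDC scale with cohort heterogeneity rather than with measurement
error. Cohort summaries (`summarize_cohort()`) take the median over trials
per subject (lower median for even counts), report cohort mean ± SD of the
medians, compute the limb symmetry index `LSI = non-dominant/dominant·100`
per subject from those medians (85--115% is the physiological band), and
average ICCs over the acceleration-based and angular-velocity-based
parameter families.

`sample_size_reliability()` is the Walter--Eliasziw--Donner approximation.
With minimum acceptable reliability 0.3, expected reliability 0.7, two-sided
α = 0.05, power 0.8 and k = 3 repetitions it returns 16 subjects: the
closed form evaluates to 16.003 and is rounded to the nearest integer
(a one-sided α would give 13; both conventions are selectable).

## The synthetic-signal module

The generators produce the statistical and morphological structure the
detectors assume, no more:

* **SLS** (`simulate_sls()`): tibia pitch follows a raised-cosine descent
  over 2.2 s to a configurable peak (default 75°) with a 35% linear
  component giving a ~12 °/s movement-initiation velocity, then a cubic
  Hermite return over 1.2 s that crosses the start angle at ~35 °/s,
  overshoots 4° into hyperextension and settles back. Profiles with zero
  onset and zero crossing velocity would make threshold detection of the
  true instants ill-posed (unbounded latency at any finite threshold);
  brisk initiation and an overshooting return are what decisive squatting
  looks like. Gravity and the earth field are rotated into the moving
  frame analytically; postural sway enters as translational acceleration
  on the transverse axes -- slow (0.2--1.3 Hz) and small (0.07 m/s²) during
  bipodal stance, larger (0.55 m/s² mediolateral) in a 1--4 Hz band during
  the squat. `sway_scale = 0` simulates a perfectly steady subject for
  exact-recovery tests.
* **CHT** (`simulate_cht()`): the foot angular-velocity magnitude carries a
  symmetric tent peaking exactly at each take-off (slopes ±30 rad/s², so
  the smoothed derivative first crosses −0.6 rad/s² at the true instant)
  and a 22 rad/s landing burst decaying with a 22 ms time constant -- fast
  enough that its derivative re-crosses the take-off threshold only inside
  the refractory period. The acceleration magnitude is zero in flight
  (free fall), rises after landing with a 12 ms time constant into an
  impact-loading envelope peaking ~40 ms after contact, and returns to
  zero exactly at the next take-off. Flight and contact durations are
  per-hop parameters, so temporal features are linear in the
  configuration by construction.
* **CMJ** (`simulate_cmj_grf()`): the GRF is built from analytic
  centre-of-mass acceleration phases -- a sin² unweighting pulse (0.35 s,
  1.26 m/s² deep, chosen gentle so that the first inflection at a quarter
  of the dip carries near-zero centre-of-mass velocity and the segmented
  net impulse matches `sqrt(2·g·h)` to within ~1%), a sinusoidal
  propulsion pulse whose amplitude is solved numerically from the
  requested jump height, and an exactly zero flight phase.
* **Cohorts** (`simulate_cohort()`): trial-level parameter values drawn
  with prescribed between-subject and within-subject SDs, so the true ICC
  is `σ_b²/(σ_b² + σ_w²)` by construction.

Default sensor noise is white, with SDs of 0.05 m/s² (accelerometer),
0.0035 rad/s (gyroscope), 0.5 µT (magnetometer) and 2 N (force plate), plus
a constant gyroscope bias of (0.01, −0.02, 0.005) rad/s -- consumer-MEMS
figures for this sensor class. All draws come from an explicitly seeded
generator; identical configuration and seed give bit-identical recordings,
and the global RNG state is never touched.

What the generators do *not* emulate: soft-tissue artefact, sensor
mounting slip, magnetic disturbance fields, scale-factor or cross-axis
errors, multi-segment kinematics (the tibia rotates about a single axis),
and the translational acceleration that a real tibia sensor picks up from
knee translation. Passing the synthetic suites therefore demonstrates that
the algorithms implement their definitions correctly and are robust to
sensor noise at realistic levels -- not that the thresholds are optimal for
any particular hardware on real athletes.

## Test problem sizes

The test suite verifies noiseless recovery to ±1 sample and noisy recovery
to ±10 ms on 100 seeded trials per task; prediction-ellipse coverage on
10⁵ isotropic Gaussian points (0.90 ± 0.01); ICC equality with an
independent `aov`-based sums-of-squares oracle to 10⁻¹²; ICC point-estimate
recovery (±0.03) and CI coverage (93--97%) over 200 replicate cohorts of
100 subjects × 3 trials at true ICCs 0.3/0.5/0.7/0.9; and the CMJ
impulse-momentum identity to 2% across jump heights of 0.2--0.4 m. These
sizes make the full suite run in about a minute on one CPU while leaving
Monte-Carlo margins well clear of the assertion bounds.

## Known limitations

* The complementary-filter formulation is one defensible reading of
  "confidence-weighted" accelerometer/magnetometer fusion; other filters
  (Madgwick, Kalman) would give slightly different pitch traces and hence
  slightly different SLS segmentations on real data.
* The SLS start rule's one-sided ×10 scaling is a documented
  interpretation; the presentation-only variant is configurable and its
  latency cost is explained above.
* Reliability statistics assume complete subject × trial matrices;
  subjects with missing trials are excluded listwise (with a message).
* The pipeline deliberately stops short of joint kinetics: no knee moments
  or 3D joint angles are estimated from the two sensors.
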