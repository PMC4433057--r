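---
title: "Methods: magnetometer-free joint RoM examination and its reliability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnetometer-free joint RoM examination and its reliability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romexam)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
parameters matter, and what the synthetic-data tests do and do not show
about real examinations.

## The examination model

A neutral-zero RoM examination moves the distal segment of a joint from a
defined neutral start posture about a defined axis to the end of its range;
the maximum rotation angle is the RoM. The package encodes a whole-body
catalog of 40 such examination angles over 13 sensor sites
(`load_catalog()`): 10 active examinations of the cervical, thoracic and
lumbar spine (screening) and 30 passive examinations of shoulder, elbow,
wrist, hip and knee (diagnostics). Each entry names the sensor pair (or the
single distal sensor), the joint-coordinate-system axis, a sign mapping the
signed component onto the anatomical nomenclature of the side, and two
literature reference ranges used for validity flags. Distance-based
examination items (finger–floor and the like) are out of scope; the catalog
is angle-only.

Two trunk pairings are not uniquely determined by the sensor complement and
are configuration, not anatomy: cervical examinations use the forehead
sensor against Th4, thoracic/lumbar examinations Th4 against L5/S1 — the
only physically sensible assignment with exactly those three head/trunk
sites. Forearm pronation/supination is measured at the forearm sensor (the
hand sensor over-reads through wrist coupling and serves the wrist
examinations).

## Orientation estimation without a magnetometer

Indoor examination rooms make magnetometers unreliable, so the estimator
uses angular rate and acceleration only. Conventions, fixed package-wide:
Hamilton quaternions, scalar first, passive sensor→world; world frame
right-handed with Z up; a resting accelerometer reads the gravitational
reaction $(0,0,9.81)\,\mathrm{m/s^2}$.

Propagation is strapdown integration by the quaternion exponential,
$q_{k+1} = q_k \otimes \exp(\tfrac12\,\omega_k\,\Delta t)$, exact for a
constant rate over a step — a pure-integration trace of a constant-rate
rotation matches the closed form to $10^{-13}$ degrees over 10 s at 100 Hz.
Tilt is stabilised by a complementary correction: when the accelerometer
norm is within `accel_gate` (default 0.5 m/s²) of gravity, the estimate is
rotated toward re-aligning the measured specific force with world +Z by the
fraction `correction_gain` (default 0.02 per sample at 100 Hz, i.e. a time
constant of about 0.5 s). The correction axis is horizontal by
construction: heading is never touched, because without a magnetometer yaw
is unobservable — an injected constant yaw offset propagates through the
filter unchanged, which the tests assert as a property. A Kalman filter
would add states and tuning without changing what is observable in these
quasi-static examinations; the complementary form keeps the contract small
and testable. Heading drift within one repetition is accepted: repetitions
last seconds and the system re-initialises at every repetition start.

With a 0.5 °/s horizontal gyro bias and 30 s of standstill, pure
integration drifts 15° while the corrected filter stays below 0.25°; under
0.2 °/s rate noise the corrected estimate tracks a moving trace within
0.5°. These are the package's acceptance numbers, recomputed by
`scripts/acceptance.R`.

## Calibration at the neutral posture

The simplified anatomical calibration assumes the segment stands exactly in
the catalog's neutral orientation during the initial static window (1.0 s
by default, matching re-initialisation at each examination start). The
sensor's inclination is then measured from gravity, and the remaining free
heading is taken from the *expected* sensor orientation — the site's
neutral segment axes composed with the prescribed mounting orientation.
This is a deliberate design decision with a sharp consequence:

* **Prescribed mounting cancels exactly.** Because the expected orientation
  includes the protocol's mounting, an arbitrary *known* mounting rotation
  changes no downstream joint angle (the tests demand < 0.2° noise-free,
  and the chain is in fact exact). A mounting rotation about gravity is
  *not* observable from a single static window, so this cancellation is
  only possible because the mounting is protocol knowledge — the simulator
  records it in the run manifest exactly as an operator would know how the
  sensor was strapped on.
* **Posture deviation is not correctable.** If the subject starts away from
  neutral, the calibration attributes the observable part of that deviation
  to the sensor, and the measurement is shifted by about the deviation (a
  10° start offset shifts the reported RoM by ≈ 10°). The tool inherits
  this limitation of the neutral-zero start; `residual_tilt` only flags
  motion during the window, not a wrong posture.

## Joint angles and RoM

Joint rotation is either the neutral-referenced relative orientation of the
two segment estimates (two-sensor mode) or the distal segment against its
own start (single-sensor mode). Decomposition follows the Grood–Suntay
joint coordinate system: flexion about the proximal segment's mediolateral
axis, rotation about the distal long axis, abduction as the deviation of
the angle between those axes from 90°, which is an intrinsic
$e_1$–floating–$e_3$ Cardan sequence. Compose-then-decompose round-trips to
$10^{-9}$ degrees away from the $|\beta| \to 90^\circ$ singularity; near it
the result is flagged (`gimbal`), never an error, since no catalog
examination approaches it. "Measurement in the plane of motion" is realised
as *taking the examination's JCS component*, not as a geometric projection;
for the planar motions of these examinations the two coincide. Left/right
semantics are carried by the catalog's per-entry sign; the reported RoM is
the unsigned magnitude of the extreme in the named direction, and both
extremes are retained so one recording can serve paired nomenclatures.

## The simulator: what it emulates, and what it does not

The generator draws, per subject $s$ and angle $a$, a true RoM
$\theta_{sa} \sim N(\mu_a, \sigma_s^2)$; each repetition executes
$\theta_{sa} + N(0, \sigma_{rep}^2)$; the examiner's rating is
$\theta_{sa} + b_r + J_{sra} + \kappa(\text{executed} - \theta_{sa})$
rounded to the rating grid, with judgement error $J_{sra}$ drawn *once* per
subject × rater × angle. The judgement-once structure follows the observed
examiner behaviour of keeping ratings nearly constant over immediate
repetitions (with `rater_follow` $\kappa = 0.3$ of the execution deviation
leaking through before 5° rounding); it is also what makes the
average-measures ICC analytically tractable: with rater noise on the cell
mean, ICC(3,k) converges to $\sigma_s^2/(\sigma_s^2 + \sigma_e^2/k)$, which
the acceptance suite recovers as $100/103$ at $n = 2000$.

Defaults are the study conditions this class of examination is run under:
20 subjects, 3 raters, 5 repetitions, a 5° examiner rating grid, 3°
execution SD, between-subject SD 10°, rater biases $(-6, 0, 6)$° and
judgement SDs $(8, 10, 12)$° — chosen once so the simulated examiner ICC
spans roughly 0.3–0.9, the range such studies report, while per-rater
sensor-set offsets $(-2, 0, 2)$° keep the measurements "biased but precise"
(column offsets do not depress a consistency ICC). Motion profiles are
smoothstep ramp–hold–return (defaults 1 s static pause, 2 s up, 1 s hold,
2 s return) — any smooth quasi-static profile works; study-scale runs use
50 Hz and slightly shorter phases to keep simulation cheap (the acceptance
runs state their sizes: 40 single-repetition recordings; 200 × 3 × 5 and
20 × 3 × 10 × 5 repetition studies).

The streams are the exact inverse of the fusion model: body-frame rates
from the quaternion increments (re-integration reproduces the trace to
0.05°), gravity rotated into the sensor frame, then gyro noise/bias,
accelerometer noise, an 8°-amplitude slow sinusoidal soft-tissue rotation
if enabled, and start-posture offsets. Deliberately *not* simulated:
translational segment acceleration (examinations are quasi-static; the
accel gate exists for robustness, and a flagged extension could add it),
magnetometer channels, anthropometrics, and the examiner's physical
influence on passive motion execution. Consequently, passing tests show the
*processing chain* is correct and the *statistical layer* recovers known
structure; they do not certify accuracy on real tissue, where soft-tissue
artifact and examiner handling dominate the error budget of passive
examinations.

## Reliability statistics

Per cell (subject × rater × angle), the comparator is the mean of the five
repetitions; repeatability is the mean within-repetition sample SD (n−1
denominator throughout — the small-sample convention). Note the mean of a
5-sample SD estimates $c_4(5)\,\sigma \approx 0.94\,\sigma$; when the
acceptance suite *recovers* an injected 3° execution SD it divides by
$c_4(5)$, while the reporting table prints the raw mean SD exactly as an
examination study would.

Inter-rater reliability is ICC(3,k) — two-way mixed, average measures,
consistency — computed from closed-form mean squares and cross-checked in
the tests against an independently coded ANOVA route (`stats::aov`).
Degenerate tables (no between-subject variance) return NaN with a flag;
negative estimates are returned raw with a warning and floored to 0 only in
the rendered report, preserving information while matching how such tables
are printed. Agreement uses Bland–Altman mean difference and 95% limits
$\text{MDiff} \pm 1.96\,\text{SD}$, with the panel ordered as such studies
plot them: each examiner against their own measurement, then all
measurement pairs, then all examiner pairs ($k + 2\binom{k}{2} = 9$ panels
for $k = 3$). Decision rules: ICC ≥ 0.8 acceptable (inclusive); |MDiff| <
5° acceptable (strict). Subjects with a missing cell are dropped per angle
and counted, mirroring how real studies handle subjects excluded for single
joints. Confidence intervals for the ICC are intentionally out of scope.

## Numerical choices and edge cases

* Quaternion traces are kept sign-continuous; unit norm is enforced to
  $10^{-9}$ at every step.
* The rating grid rounds half-up (73.2° on a 5° grid → 75°) for
  determinism.
* Validity flags treat reference boundaries inclusively; a single reference
  value is a degenerate range.
* All randomness flows from explicit seeds; identical spec + seed gives
  byte-identical sheets, streams and manifests, and the simulator restores
  the caller's RNG state.
* Streams must be uniformly sampled (1 ns tolerance); NaN samples are
  rejected with their index; a non-static calibration window is an error
  advising to repeat the neutral posture.

## Known limitations

Functional (movement-based) calibration is not implemented — the simplified
neutral-posture calibration is the method under study, and its
start-posture sensitivity is reproduced, not corrected. Soft-tissue
artifact is simulated but not compensated. A subject who cannot reach the
neutral-zero start is not detectable from the data; only high
`residual_tilt` (motion during the window) is flagged.
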