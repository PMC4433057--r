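# romexam

Joint range-of-motion (RoM) examination with body-worn inertial measurement
units (IMUs), reimplemented end to end as an R package: the magnetometer-free
measurement chain, the whole-body examination catalog, the reliability
statistics used to evaluate such a tool against human examiners, and a
seeded synthetic examination simulator so the whole chain can be exercised
and validated without hardware or subject data.

## Who this is for

Researchers in movement analysis and occupational health who work with
neutral-zero RoM examinations (active screening of the spine, passive
diagnostics of the extremities) and want a reproducible, scriptable pipeline
for (a) turning raw gyroscope/accelerometer streams into anatomical joint
angles and per-repetition RoM values, and (b) quantifying repeatability,
inter-rater reliability and agreement of such measurements.

## What it computes

**Measurement chain** (per repetition of one examination):

1. *Neutral calibration.* Over the first second the subject holds the
   examination's neutral start posture. Sensor inclination is measured from
   gravity, the free heading is taken from the expected segment orientation
   (no magnetometer is used anywhere; magnetic disturbance is avoided by
   design). This yields the sensor-to-segment rotation.
2. *Orientation estimation.* Strapdown integration of the angular rate by
   the quaternion exponential `q_{k+1} = q_k ⊗ exp(½ ω_k Δt)`, with a
   gravity-gated complementary tilt correction (default gain 0.02/sample at
   100 Hz; correction axis is horizontal, so heading is never touched).
3. *Joint angles.* Either the neutral-referenced relative orientation of
   two sensors on adjacent segments (e.g. upper arm and forearm for elbow
   flexion) or one sensor against its own start orientation (e.g. forearm
   for shoulder internal/external rotation), decomposed in the
   Grood–Suntay joint coordinate system into flexion `α`, abduction `β`,
   rotation `γ` (an intrinsic e1–floating–e3 Cardan sequence).
4. *RoM extraction.* Minimum and maximum of the examination's JCS component
   are stored; the extreme in the direction named by the anatomical
   nomenclature (catalog `sign`) is the reported RoM.

**Examination catalog**: 40 angles (10 active spine, 30 passive extremity
examinations), 13 sensor sites, each entry carrying the sensor pair, JCS
axis, sign convention and two literature reference ranges.

**Reliability layer**: within-repetition sample SD (repeatability), the
two-way mixed average-measures intraclass correlation

    ICC(3,k) = (BMS − EMS) / BMS

from the subjects × raters ANOVA mean squares (decision rule: ≥ 0.8 is
acceptable), and Bland–Altman agreement `MDiff ± 1.96·SD` of per-subject
rater differences (|MDiff| < 5° is an acceptable systematic difference).

**Simulator**: per-subject true RoM ~ N(μ, σs²), per-repetition execution
noise, per-rater bias and judgement error with a 5° rating grid, sensor
noise/bias, soft-tissue sensor rotation and start-posture deviation; it
emits the same stream/sheet formats the processing chain consumes.

## Worked example

```r
library(romexam)
catalog <- load_catalog()
lookup_examination(catalog, "cervical_rotation_L")$ref_range_2
#> [1] 70

# one noise-free elbow-flexion repetition to 140 degrees, measured end to end
exam   <- lookup_examination(catalog, "elbow_flexion_R")
script <- motion_script("elbow_flexion_R", peaks = 140, sampling_rate = 100)
kin    <- simulate_segment_kinematics(script, exam, catalog)
streams <- lapply(setNames(nm = names(kin$repetitions[[1]]$traces)),
  function(s) synthesize_imu(kin$repetitions[[1]]$traces[[s]],
                             noise_model(gyro_noise_sd = 0, accel_noise_sd = 0),
                             site_id = s))
process_recording(list(angle_id = "elbow_flexion_R",
                       repetitions = list(list(rep = 1L, streams = streams))),
                  catalog)
#>          angle_id rep measured_rom_deg       min_deg max_deg residual_tilt_deg
#> 1 elbow_flexion_R   1              140 -1.208611e-13     140                 0
```

The measured RoM equals the commanded 140° to numerical precision: with
noise-free sensors the strapdown/decomposition chain is exact.

A full simulated inter-rater study (20 subjects, 3 raters, 5 repetitions)
and its analysis:

```r
study <- run_study(cohort_spec(seed = 1), "cervical_flexion",
                   script_args = list(sampling_rate = 50))
icc_3k(rating_table(study$measurement_sheet, "cervical_flexion"))
#> ICC(3,k) = 0.994 (BMS 257.82, EMS 1.54, n = 20, k = 3) [acceptable]
icc_3k(rating_table(study$examiner_sheet, "cervical_flexion"))
#> ICC(3,k) = 0.562 (BMS 238.68, EMS 104.60, n = 20, k = 3)
```

The sensor chain is precise within a rater (high measurement ICC) while the
simulated examiners carry judgement error and a 5° rating grid, so their
ICC is lower — the qualitative pattern such a measurement tool is meant to
produce.

## Command line

A thin front-end over the same functions lives in `exec/romexam`:

```sh
Rscript exec/romexam simulate --config run.yaml --seed 1
Rscript exec/romexam process  --dir romexam_run
Rscript exec/romexam analyze  --dir romexam_run
Rscript exec/romexam report   --stats romexam_run/stats/stats.json
```

`simulate` writes one stream CSV (`t,gx,gy,gz,ax,ay,az`) per site and
repetition plus the examiner sheet, ground truth and a manifest; `process`
writes the results sheet; `analyze` writes `stats.json` and Bland–Altman
plot-data CSVs; `report` renders a markdown summary with the two decision
rules applied.

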