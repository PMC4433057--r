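test_that("Grood-Suntay decomposition of elementary rotations", {
  id <- grood_suntay_decompose(c(1, 0, 0, 0))
  expect_equal(unlist(id[1, 1:3]), c(flexion = 0, abduction = 0, rotation = 0))
  # pure 30 deg rotation about the flexion axis (segment y)
  q <- quat_from_axis_angle(c(0, 1, 0), 30 * pi / 180)
  d <- grood_suntay_decompose(q)
  expect_equal(c(d$flexion, d$abduction, d$rotation), c(30, 0, 0),
               tolerance = 1e-9)
  # long-axis rotation and floating-axis abduction land on their components
  d <- grood_suntay_decompose(quat_from_axis_angle(c(0, 0, 1), 0.4))
  expect_equal(d$rotation, 0.4 * 180 / pi, tolerance = 1e-9)
  expect_equal(c(d$flexion, d$abduction), c(0, 0), tolerance = 1e-9)
  d <- grood_suntay_decompose(quat_from_axis_angle(c(-1, 0, 0), 0.3))
  expect_equal(d$abduction, 0.3 * 180 / pi, tolerance = 1e-9)
})

test_that("compose-then-decompose round-trips exactly away from gimbal proximity", {
  q <- jcs_compose(20, 10, 5)
  d <- grood_suntay_decompose(q)
  expect_equal(c(d$flexion, d$abduction, d$rotation), c(20, 10, 5),
               tolerance = 1e-9)
  set.seed(7)
  f <- stats::runif(200, -170, 170)
  a <- stats::runif(200, -75, 75)
  r <- stats::runif(200, -170, 170)
  d <- grood_suntay_decompose(jcs_compose(f, a, r))
  expect_lt(max(abs(d$flexion - f), abs(d$abduction - a),
                abs(d$rotation - r)), 1e-9)
  expect_false(any(d$gimbal))
  # near the singularity the gimbal flag is raised, not an error
  d85 <- grood_suntay_decompose(jcs_compose(10, 85, 10))
  expect_true(d85$gimbal)
})

test_that("neutral calibration is exact for an aligned static sensor", {
  site <- lookup_site(CATALOG, "th4")
  st <- static_stream()
  cal <- calibrate_neutral(st, site)
  expect_lt(quat_angle_deg(cal$q_sensor_to_segment, c(1, 0, 0, 0)), 1e-9)
  expect_lt(cal$residual_tilt, 1e-9)
  # motion in the window is reported as a calibration failure
  t <- seq(0, 2, by = 0.01)
  moving <- synthesize_imu(
    orientation_trace(t, quat_from_axis_angle(c(0, 1, 0), 1.2 * t)),
    noise_free())
  expect_error(calibrate_neutral(moving, site), "neutral")
})

test_that("prescribed mounting rotations cancel after calibration", {
  set.seed(8)
  worst <- 0
  for (a in c("elbow_flexion_L", "cervical_rotation_R", "wrist_abduction_R",
              "shoulder_external_rotation_L", "knee_flexion_R")) {
    exam <- lookup_examination(CATALOG, a)
    sites <- c(exam$distal_site, exam$proximal_site)
    mnt <- lapply(stats::setNames(nm = sites), function(s) random_unit_quat())
    plain <- measure_examination(a, 60)
    mounted <- measure_examination(a, 60, mounting = mnt)
    worst <- max(worst, abs(mounted$measured_rom_deg - plain$measured_rom_deg))
  }
  expect_lt(worst, 0.2)
  # the spec'd special case: 90 deg mounting about the segment long axis
  mnt <- list(forearm_L = quat_from_axis_angle(c(0, 0, 1), pi / 2))
  r <- measure_examination("shoulder_external_rotation_L", 85, mounting = mnt)
  expect_equal(r$measured_rom_deg, 85, tolerance = 0.2)
})

test_that("a start-posture deviation shifts the measured RoM by about itself", {
  r <- measure_examination("elbow_flexion_L", 120, start_deg = 10)
  expect_equal(r$measured_rom_deg, 110, tolerance = 1)
})

test_that("joint angle traces honour both measurement modes", {
  # no relative motion in two-IMU mode: all components zero
  exam <- lookup_examination(CATALOG, "knee_flexion_L")
  t <- seq(0, 2, by = 0.02)
  qn <- matrix(rep(c(1, 0, 0, 0), length(t)), ncol = 4, byrow = TRUE)
  traces <- list(upper_leg_L = orientation_trace(t, qn),
                 lower_leg_L = orientation_trace(t, qn))
  cal <- lapply(stats::setNames(nm = names(traces)), function(s)
    calibrate_neutral(static_stream(site_id = s),
                      lookup_site(CATALOG, s)))
  jt <- joint_angle_trace(exam, traces, cal, CATALOG)
  expect_lt(max(abs(jt$flexion), abs(jt$abduction), abs(jt$rotation)), 1e-9)
  # missing site is a configuration error naming the site
  expect_error(joint_angle_trace(exam, traces["lower_leg_L"], cal, CATALOG),
               "upper_leg_L")
  # end-to-end: two-IMU elbow flexion and single-IMU shoulder rotation
  expect_equal(measure_examination("elbow_flexion_R", 140)$measured_rom_deg,
               140, tolerance = 0.1)
  expect_equal(
    measure_examination("shoulder_internal_rotation_L", 90)$measured_rom_deg,
    90, tolerance = 0.1)
})

test_that("extract_rom maps signed extremes onto paired nomenclatures", {
  t <- seq(0, 1, length.out = 101)
  comp <- -40 + 115 * sin(pi * t)    # spans about -40 .. +75
  comp[1] <- -40; comp[101] <- 75    # make the extremes exact
  trace <- structure(list(angle_id = "cervical_rotation_L", t = t,
                          flexion = comp * 0, abduction = comp * 0,
                          rotation = comp, gimbal = rep(FALSE, 101)),
                     class = "rom_joint_angle_trace")
  left <- lookup_examination(CATALOG, "cervical_rotation_L")   # sign +1
  right <- lookup_examination(CATALOG, "cervical_rotation_R")  # sign -1
  expect_equal(extract_rom(trace, left)$reported_rom_deg, 75)
  expect_equal(extract_rom(trace, right)$reported_rom_deg, 40)
  expect_equal(extract_rom(trace, left)$min_deg, -40)
  # constant zero trace
  trace0 <- trace; trace0$rotation <- comp * 0
  r0 <- extract_rom(trace0, left)
  expect_equal(c(r0$min_deg, r0$max_deg, r0$reported_rom_deg), c(0, 0, 0))
  # empty trace errors
  tempty <- trace; tempty$rotation <- numeric(0)
  expect_error(extract_rom(tempty, left), "empty")
})
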