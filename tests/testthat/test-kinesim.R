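test_that("segment kinematics follow the commanded profile peaks", {
  exam <- lookup_examination(CATALOG, "elbow_flexion_L")
  s <- motion_script("elbow_flexion_L", peaks = 140, sampling_rate = 50)
  kin <- simulate_segment_kinematics(s, exam, CATALOG)
  expect_equal(kin$true_rom, 140)
  # zero-amplitude profile: distal orientation constant
  s0 <- motion_script("elbow_flexion_L", peaks = 0, sampling_rate = 50)
  kin0 <- simulate_segment_kinematics(s0, exam, CATALOG)
  qd <- kin0$repetitions[[1]]$traces[["forearm_L"]]$q
  expect_lt(max(quat_angle_deg(qd, qd[1, ])), 1e-12)
  expect_equal(kin0$true_rom, 0)
  # five repetitions read back their peaks in order
  s5 <- motion_script("elbow_flexion_L", peaks = c(138, 139, 140, 141, 142),
                      sampling_rate = 50)
  kin5 <- simulate_segment_kinematics(s5, exam, CATALOG)
  expect_equal(kin5$true_rom, c(138, 139, 140, 141, 142))
  expect_length(kin5$repetitions, 5L)
  # domain guard
  expect_error(motion_script("x", peaks = 200), "180")
  expect_error(simulate_segment_kinematics(s, lookup_examination(
    CATALOG, "knee_flexion_L"), CATALOG), "exam is")
})

test_that("synthesised IMU statics match the world convention", {
  st <- static_stream()
  expect_lt(max(abs(st$omega)), 1e-12)
  expect_equal(unname(st$accel[1, ]), c(0, 0, 9.81), tolerance = 1e-12)
  # constant 90 deg/s rotation about world Z: |omega| = pi/2 everywhere
  t <- seq(0, 1, by = 0.01)
  tr <- orientation_trace(t, quat_from_axis_angle(c(0, 0, 1), pi / 2 * t))
  st2 <- synthesize_imu(tr, noise_free())
  expect_equal(sqrt(rowSums(st2$omega^2)), rep(pi / 2, length(t)),
               tolerance = 1e-9)
})

test_that("re-integrating emitted angular rate reproduces a smooth trace", {
  t <- seq(0, 10, by = 0.01)
  q <- quat_multiply(
    quat_from_axis_angle(c(0, 0, 1), 0.8 * sin(0.7 * t)),
    quat_from_axis_angle(c(0, 1, 0), 0.5 * sin(1.1 * t + 0.3)))
  tr <- orientation_trace(t, q)
  st <- synthesize_imu(tr, noise_free())
  est <- estimate_orientation(st, tr$q[1, ], filter_config(correction_gain = 0))
  expect_lt(max(quat_angle_deg(est$q, tr$q)), 0.05)
})

test_that("rating grid rounds half-up to the nearest multiple", {
  expect_equal(rating_round(73.2, 5), 75)
  expect_equal(rating_round(72.4, 5), 70)
  expect_equal(rating_round(72.5, 5), 75)
  expect_equal(rating_round(-72.5, 5), -70)  # half-up, not half-away
  expect_equal(rating_round(73.2, 0), 73.2)
})

test_that("study design has the stated structure and degenerate-noise limit", {
  co <- cohort_spec(n_subjects = 3, n_raters = 3, rep_sd = 0, rater_sd = 0,
                    rater_bias = 0, sensor_bias = 0, rating_grid = 0,
                    rater_follow = 0, seed = 5)
  des <- simulate_design(co, c("cervical_flexion", "knee_flexion_L"),
                         CATALOG, noise_free())
  # exactly n_repetitions rows per subject x rater x angle
  counts <- table(des$design$subject, des$design$rater, des$design$angle_id)
  expect_true(all(counts == co$n_repetitions))
  # all noise zero: every rating equals the subject's true RoM
  merged <- merge(des$design, des$truth)
  expect_equal(merged$rating_deg, merged$true_rom_deg, tolerance = 1e-12)
  expect_equal(merged$executed_deg, merged$true_rom_deg, tolerance = 1e-12)
})

test_that("identical cohort spec and seed reproduce identical output", {
  co <- cohort_spec(n_subjects = 2, seed = 77)
  d1 <- simulate_design(co, "wrist_flexion_L", CATALOG, noise_model(seed = 3))
  d2 <- simulate_design(co, "wrist_flexion_L", CATALOG, noise_model(seed = 3))
  expect_identical(d1, d2)
  s1 <- simulate_study(co, "wrist_flexion_L", CATALOG, noise_model(seed = 3))
  s2 <- simulate_study(co, "wrist_flexion_L", CATALOG, noise_model(seed = 3))
  expect_identical(s1$recordings, s2$recordings)
  # and the simulator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_design(co, "wrist_flexion_L", CATALOG,
                                         noise_model(seed = 3)))
  expect_identical(rnorm(1), before)
})

test_that("soft-tissue artifact perturbs the sensor but not the segment truth", {
  t <- seq(0, 4, by = 0.02)
  tr <- orientation_trace(t, matrix(rep(c(1, 0, 0, 0), length(t)),
                                    ncol = 4, byrow = TRUE))
  st <- synthesize_imu(tr, noise_free(soft_tissue_rot_amp = 8, seed = 9))
  # the sensor now moves: angular rate is no longer zero
  expect_gt(max(abs(st$omega)), 1e-3)
  # and the gravity direction wanders by up to the rotation amplitude
  dirs <- st$accel / sqrt(rowSums(st$accel^2))
  ang <- acos(pmin(1, dirs[, 3])) * 180 / pi
  expect_gt(max(ang), 1)
  expect_lt(max(ang), 8.5)
})
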