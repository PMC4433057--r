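# Synthetic examination simulator.
#
# Produces ground-truth segment kinematics, IMU sensor streams and examiner
# rating sheets with the statistical structure a RoM reliability study
# assumes: per-subject true RoM (between-subject variance), per-repetition
# execution noise (within-subject), per-rater judgement error and bias plus
# a rating grid (examiners round to a 5 degree scale), sensor noise/bias,
# soft-tissue sensor rotation and start-posture deviation. Everything is
# seeded and reproducible.

# run expr with a private RNG state, restoring the caller's state afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

# stable sub-seed derivation (Weyl-style), kept below 2^31
.sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483563)
}

#' IMU stream container
#'
#' @param site_id sensor site token.
#' @param t sample times, seconds, uniform at `1/sampling_rate`.
#' @param omega n x 3 angular rate in the sensor frame, rad/s.
#' @param accel n x 3 specific force in the sensor frame, m/s^2.
#' @param sampling_rate Hz.
#' @return a `rom_imu_stream`.
#' @export
imu_stream <- function(site_id, t, omega, accel, sampling_rate) {
  omega <- .as_vec3_mat(omega); accel <- .as_vec3_mat(accel)
  stopifnot(sampling_rate > 0, length(t) == nrow(omega),
            nrow(omega) == nrow(accel))
  dt <- 1 / sampling_rate
  if (max(abs(diff(t) - dt)) > 1e-9)
    stop("IMU stream time base must be uniform at 1/sampling_rate (1e-9 s)")
  structure(list(site_id = site_id, t = as.numeric(t), omega = omega,
                 accel = accel, sampling_rate = sampling_rate),
            class = "rom_imu_stream")
}

#' Sensor noise / artefact model
#'
#' @param gyro_noise_sd white angular-rate noise, deg/s per axis.
#' @param gyro_bias constant rate bias, deg/s; length 1 or 3.
#' @param accel_noise_sd white accelerometer noise, m/s^2 per axis.
#' @param soft_tissue_rot_amp amplitude of a slow sinusoidal sensor-on-skin
#'   rotation, degrees (surface-mounted sensors have been observed to move
#'   by about 8 degrees of rotation relative to the bone).
#' @param soft_tissue_freq frequency of that rotation, Hz.
#' @param start_posture_offset_sd SD of the deviation of the start posture
#'   from the defined neutral, degrees. A neutral-zero method cannot observe
#'   this deviation; it shifts the measured RoM.
#' @param seed RNG seed for the sensor-noise draws.
#' @return a `rom_noise_model`.
#' @export
noise_model <- function(gyro_noise_sd = 0.2, gyro_bias = 0,
                        accel_noise_sd = 0.05, soft_tissue_rot_amp = 0,
                        soft_tissue_freq = 0.25,
                        start_posture_offset_sd = 0, seed = 1L) {
  if (length(gyro_bias) == 1L) gyro_bias <- rep(gyro_bias, 3L)
  stopifnot(gyro_noise_sd >= 0, accel_noise_sd >= 0,
            soft_tissue_rot_amp >= 0, start_posture_offset_sd >= 0,
            length(gyro_bias) == 3L)
  structure(list(gyro_noise_sd = gyro_noise_sd, gyro_bias = gyro_bias,
                 accel_noise_sd = accel_noise_sd,
                 soft_tissue_rot_amp = soft_tissue_rot_amp,
                 soft_tissue_freq = soft_tissue_freq,
                 start_posture_offset_sd = start_posture_offset_sd,
                 seed = as.integer(seed)), class = "rom_noise_model")
}

#' Simulated cohort / study design
#'
#' Defaults emulate the study conditions of a whole-body RoM inter-rater
#' examination: 20 subjects, 3 raters, 5 repetitions per examination, a
#' 5 degree examiner rating grid, and rater error levels chosen so simulated
#' ICC values span roughly 0.4-0.95.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param true_rom_mean,true_rom_sd between-subject distribution of the true
#'   RoM, degrees. Either single numbers (applied to every angle) or named
#'   vectors per angle_id; `NULL` means "use the catalog reference value".
#' @param rep_sd within-subject execution SD per repetition, degrees.
#' @param rater_bias systematic rating offset per rater, degrees (length
#'   `n_raters`).
#' @param rater_sd per-rater judgement SD, degrees (length `n_raters`). The
#'   judgement error is drawn once per subject x rater x angle: examiners
#'   tend to keep their rating constant over immediate repetitions.
#' @param rater_follow fraction of the per-repetition execution deviation
#'   that an examiner's rating follows (0 = perfectly constant rates).
#' @param rating_grid examiner rounding step, degrees; 0 = continuous scale.
#' @param sensor_bias per-rater constant measurement offset, degrees,
#'   modelling each rater's own sensor set and fixation (length `n_raters`).
#' @param n_raters number of raters (>= 2).
#' @param n_repetitions repetitions per examination.
#' @param seed RNG seed for all cohort-level draws.
#' @return a `rom_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, true_rom_mean = NULL,
                        true_rom_sd = 10, rep_sd = 3,
                        rater_bias = c(-6, 0, 6), rater_sd = c(8, 10, 12),
                        rater_follow = 0.3, rating_grid = 5,
                        sensor_bias = c(-2, 0, 2), n_raters = 3L,
                        n_repetitions = 5L, seed = 1L) {
  stopifnot(n_subjects >= 2L, n_raters >= 2L, rating_grid >= 0, rep_sd >= 0,
            n_repetitions >= 1L)
  if (length(rater_bias) == 1L) rater_bias <- rep(rater_bias, n_raters)
  if (length(rater_sd) == 1L) rater_sd <- rep(rater_sd, n_raters)
  if (length(sensor_bias) == 1L) sensor_bias <- rep(sensor_bias, n_raters)
  stopifnot(length(rater_bias) == n_raters, length(rater_sd) == n_raters,
            length(sensor_bias) == n_raters, all(rater_sd >= 0))
  structure(list(n_subjects = as.integer(n_subjects),
                 true_rom_mean = true_rom_mean, true_rom_sd = true_rom_sd,
                 rep_sd = rep_sd, rater_bias = rater_bias,
                 rater_sd = rater_sd, rater_follow = rater_follow,
                 rating_grid = rating_grid, sensor_bias = sensor_bias,
                 n_raters = as.integer(n_raters),
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)), class = "rom_cohort_spec")
}

#' Motion script for one examination recording
#'
#' Ramp-hold-return profile of the true joint angle, one repetition per
#' `peaks` entry. Each repetition starts with a static pause (used by the
#' calibration window), ramps smoothly (smoothstep) to its peak, holds, and
#' returns to the start angle.
#'
#' @param angle_id examination angle the script drives.
#' @param peaks true peak joint angle per repetition, degrees.
#' @param start_deg start angle, degrees (non-zero models a deviation from
#'   the neutral start posture).
#' @param pause_s,ramp_s,hold_s,return_s phase durations, seconds.
#' @param sampling_rate Hz.
#' @return a `rom_motion_script` with per-repetition waypoints.
#' @export
motion_script <- function(angle_id, peaks, start_deg = 0, pause_s = 1,
                          ramp_s = 2, hold_s = 1, return_s = 2,
                          sampling_rate = 100) {
  stopifnot(length(peaks) >= 1L, sampling_rate > 0, pause_s >= 0,
            ramp_s > 0, hold_s >= 0, return_s > 0)
  if (any(abs(peaks) > 180) || abs(start_deg) > 180)
    stop("domain error: waypoint angles must lie within +/-180 degrees")
  waypoints <- lapply(peaks, function(p) {
    cbind(t = cumsum(c(0, pause_s, ramp_s, hold_s, return_s)),
          angle = c(start_deg, start_deg, p, p, start_deg))
  })
  structure(list(angle_id = angle_id, peaks = as.numeric(peaks),
                 start_deg = start_deg, waypoints = waypoints,
                 n_repetitions = length(peaks),
                 inter_rep_pause = pause_s,
                 sampling_rate = sampling_rate),
            class = "rom_motion_script")
}

# evaluate one repetition's angle profile on its uniform time base
.script_profile <- function(script, rep) {
  wp <- script$waypoints[[rep]]
  if (any(diff(wp[, "t"]) <= 0)) stop("script waypoint times must increase")
  dt <- 1 / script$sampling_rate
  t <- seq(0, wp[nrow(wp), "t"], by = dt)
  theta <- numeric(length(t))
  for (i in seq_len(nrow(wp) - 1L)) {
    in_seg <- t >= wp[i, "t"] & t <= wp[i + 1L, "t"]
    u <- (t[in_seg] - wp[i, "t"]) / (wp[i + 1L, "t"] - wp[i, "t"])
    s <- u * u * (3 - 2 * u)  # smoothstep: C1-continuous, quasi-static ends
    theta[in_seg] <- wp[i, "angle"] + (wp[i + 1L, "angle"] - wp[i, "angle"]) * s
  }
  list(t = t, theta_deg = theta)
}

# segment-frame rotation axis of a JCS component (see anatomy.R)
.jcs_axis_vec <- function(jcs_axis) {
  switch(jcs_axis,
         flexion = c(0, 1, 0),
         abduction = c(-1, 0, 0),
         rotation = c(0, 0, 1),
         stop("unknown jcs_axis: ", jcs_axis))
}

#' Ground-truth segment kinematics for one examination recording
#'
#' The proximal segment is held fixed at its neutral orientation (absent in
#' single-IMU mode); the distal segment rotates about the examination's JCS
#' axis following the script profile. The true RoM of each repetition is the
#' profile's peak.
#'
#' @param script a [motion_script()] with `angle_id` matching `exam`.
#' @param exam an `ExaminationAngle` from the catalog.
#' @param catalog a `rom_catalog` (for site neutral postures).
#' @return list with one element per repetition, each holding `traces`
#'   (named list of segment-to-world `rom_orientation_trace`) and `true_rom`
#'   (the commanded peak, degrees); plus `true_rom` across repetitions.
#' @export
simulate_segment_kinematics <- function(script, exam, catalog) {
  stopifnot(inherits(script, "rom_motion_script"))
  if (!identical(script$angle_id, exam$angle_id))
    stop("script drives '", script$angle_id, "' but exam is '",
         exam$angle_id, "'")
  axis <- .jcs_axis_vec(exam$jcs_axis)
  q_nd <- .site_neutral_quat(lookup_site(catalog, exam$distal_site))
  q_np <- if (!is.null(exam$proximal_site))
    .site_neutral_quat(lookup_site(catalog, exam$proximal_site)) else NULL
  reps <- lapply(seq_len(script$n_repetitions), function(k) {
    prof <- .script_profile(script, k)
    ang <- exam$sign * prof$theta_deg * pi / 180
    qd <- quat_multiply(q_nd, quat_from_axis_angle(axis, ang))
    traces <- list()
    traces[[exam$distal_site]] <- orientation_trace(prof$t, qd)
    if (!is.null(exam$proximal_site)) {
      qp <- matrix(q_np, nrow = length(prof$t), ncol = 4L, byrow = TRUE)
      traces[[exam$proximal_site]] <- orientation_trace(prof$t, qp)
    }
    list(traces = traces, true_rom = script$peaks[k])
  })
  list(repetitions = reps, true_rom = script$peaks)
}

#' Synthesise an IMU stream from a segment orientation trace
#'
#' Inverse of the fusion model: the emitted angular rate is the body-frame
#' rate consistent with the quaternion increments (so re-integrating it
#' reproduces the trace), and the specific force is world gravity (+Z,
#' 9.81 m/s^2 reaction) rotated into the sensor frame. Segment translational
#' acceleration is not modelled: examination movements are quasi-static.
#' Mounting offset, soft-tissue rotation, noise and bias are then applied
#' per the noise model.
#'
#' @param trace segment-to-world `rom_orientation_trace`, uniformly sampled.
#' @param noise a [noise_model()].
#' @param site_id site token stamped on the stream.
#' @param mounting sensor-to-segment mounting quaternion (sensor axes
#'   relative to segment axes); identity = sensor mounted exactly on the
#'   segment axes.
#' @param seed optional seed overriding `noise$seed`.
#' @return a `rom_imu_stream`.
#' @export
synthesize_imu <- function(trace, noise = noise_model(), site_id = "sensor",
                           mounting = c(1, 0, 0, 0), seed = NULL) {
  stopifnot(inherits(trace, "rom_orientation_trace"),
            inherits(noise, "rom_noise_model"))
  n <- length(trace$t)
  if (n < 2L) stop("trace must contain at least 2 samples")
  dts <- diff(trace$t)
  dt <- dts[1]
  if (max(abs(dts - dt)) > 1e-9)
    stop("trace must be uniformly sampled")
  .with_seed(seed %||% noise$seed, {
    # sensor orientation: segment composed with mounting and soft tissue
    qs <- quat_multiply(trace$q, quat_normalize(mounting))
    if (noise$soft_tissue_rot_amp > 0) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- noise$soft_tissue_rot_amp * pi / 180 *
        sin(2 * pi * noise$soft_tissue_freq * trace$t + phase)
      qs <- quat_multiply(qs, quat_from_axis_angle(ax, ang))
    }
    qs <- .quat_continuous(qs)
    # body-frame rate over each interval (exact under piecewise-constant rate)
    dq <- quat_multiply(quat_conjugate(qs[-n, , drop = FALSE]),
                        qs[-1L, , drop = FALSE])
    omega <- quat_to_rotvec(dq) / dt
    omega <- rbind(omega, omega[n - 1L, ])
    accel <- quat_rotate(quat_conjugate(qs), c(0, 0, .GRAVITY))
    if (any(noise$gyro_bias != 0))
      omega <- omega + matrix(noise$gyro_bias * pi / 180, n, 3, byrow = TRUE)
    if (noise$gyro_noise_sd > 0)
      omega <- omega + matrix(stats::rnorm(3 * n, 0,
                                           noise$gyro_noise_sd * pi / 180),
                              n, 3)
    if (noise$accel_noise_sd > 0)
      accel <- accel + matrix(stats::rnorm(3 * n, 0, noise$accel_noise_sd),
                              n, 3)
    imu_stream(site_id, trace$t, omega, accel,
               sampling_rate = round(1 / dt, 9))
  })
}

#' Round to an examiner rating grid
#'
#' Nearest multiple of `grid`, half-up at midpoints (73.2 with a 5 degree
#' grid reads 75). `grid = 0` returns the value unchanged.
#'
#' @param x values, degrees.
#' @param grid grid step, degrees.
#' @return rounded values.
#' @export
rating_round <- function(x, grid) {
  if (grid <= 0) return(x)
  floor(x / grid + 0.5) * grid
}

#' Draw the cohort-level design of a simulated study
#'
#' Performs every statistical draw of [simulate_study()] without
#' synthesising sensor streams: per-subject true RoM, per-repetition
#' executed angle, per-rep start-posture offset, and examiner ratings.
#' Useful on its own for studying the rating statistics at large n.
#'
#' @param cohort a [cohort_spec()].
#' @param angle_ids examination angle ids to simulate.
#' @param catalog a `rom_catalog`; used for reference-based default means.
#' @param noise a [noise_model()] (start-posture offsets are cohort-level
#'   draws because they shift the measured RoM).
#' @return list with `design` (one row per subject/rater/angle/rep:
#'   executed_deg, start_offset_deg, rating_deg), `truth`
#'   (subject, angle_id, true_rom_deg).
#' @export
simulate_design <- function(cohort, angle_ids, catalog = load_catalog(),
                            noise = noise_model()) {
  stopifnot(inherits(cohort, "rom_cohort_spec"))
  get_param <- function(p, a, default) {
    if (is.null(p)) return(default)
    if (length(p) == 1L && is.null(names(p))) return(as.numeric(p))
    if (!a %in% names(p)) stop("no parameter value for angle '", a, "'")
    as.numeric(p[[a]])
  }
  .with_seed(cohort$seed, {
    truth <- NULL; rows <- NULL
    for (a in angle_ids) {
      exam <- lookup_examination(catalog, a)
      mu <- get_param(cohort$true_rom_mean, a, mean(exam$ref_range_1))
      sdv <- get_param(cohort$true_rom_sd, a, 10)
      theta <- stats::rnorm(cohort$n_subjects, mu, sdv)
      truth <- rbind(truth, data.frame(subject = seq_len(cohort$n_subjects),
                                       angle_id = a, true_rom_deg = theta))
      for (s in seq_len(cohort$n_subjects)) {
        for (r in seq_len(cohort$n_raters)) {
          judge <- stats::rnorm(1, 0, cohort$rater_sd[r])
          executed <- theta[s] + stats::rnorm(cohort$n_repetitions, 0,
                                              cohort$rep_sd)
          start_off <- cohort$sensor_bias[r] +
            stats::rnorm(cohort$n_repetitions, 0,
                         noise$start_posture_offset_sd)
          rating <- rating_round(theta[s] + cohort$rater_bias[r] + judge +
                                   cohort$rater_follow *
                                     (executed - theta[s]),
                                 cohort$rating_grid)
          rows <- rbind(rows, data.frame(
            subject = s, rater = r, angle_id = a,
            rep = seq_len(cohort$n_repetitions),
            executed_deg = executed, start_offset_deg = start_off,
            rating_deg = rating))
        }
      }
    }
    list(design = rows, truth = truth)
  })
}

#' Simulate a full examination study
#'
#' Draws the cohort design ([simulate_design()]) and synthesises the IMU
#' streams of every repetition (one recording per subject x rater x angle x
#' repetition, one stream per involved sensor site). Identical spec and seed
#' give identical output.
#'
#' @inheritParams simulate_design
#' @param noise a [noise_model()] for the sensor streams.
#' @param mounting named list `site_id -> quaternion` of sensor mounting
#'   offsets (applied to every recording); `NULL` = mounted on the segment
#'   axes.
#' @param script_args list of arguments forwarded to [motion_script()]
#'   (phase durations, sampling rate).
#' @param keep_streams if `FALSE`, recordings hold no stream data (the
#'   design and sheets are still returned); use [process_recording()] via
#'   [run_study()] to stream-and-process without storing everything.
#' @return a `rom_sim_study`: list with `design`, `truth`, `examiner_sheet`
#'   (subject, rater, angle_id, rep, rating_deg), `recordings`, `mounting`,
#'   `cohort`, `noise`, `script_args`.
#' @export
simulate_study <- function(cohort, angle_ids, catalog = load_catalog(),
                           noise = noise_model(), mounting = NULL,
                           script_args = list(), keep_streams = TRUE) {
  des <- simulate_design(cohort, angle_ids, catalog, noise)
  recs <- NULL
  if (keep_streams) {
    key <- unique(des$design[c("subject", "rater", "angle_id")])
    recs <- vector("list", nrow(key))
    for (i in seq_len(nrow(key))) {
      rows <- des$design[des$design$subject == key$subject[i] &
                           des$design$rater == key$rater[i] &
                           des$design$angle_id == key$angle_id[i], ]
      recs[[i]] <- .simulate_recording(rows, key$angle_id[i], catalog, noise,
                                       mounting, script_args,
                                       base_seed = cohort$seed, rec_index = i)
    }
  }
  structure(list(design = des$design, truth = des$truth,
                 examiner_sheet = des$design[c("subject", "rater", "angle_id",
                                               "rep", "rating_deg")],
                 recordings = recs, mounting = mounting, cohort = cohort,
                 noise = noise, script_args = script_args),
            class = "rom_sim_study")
}

# one recording = all repetitions of one subject x rater x angle;
# each repetition gets its own stream set (the system re-calibrates at every
# repetition start)
.simulate_recording <- function(rows, angle_id, catalog, noise, mounting,
                                script_args, base_seed, rec_index) {
  exam <- lookup_examination(catalog, angle_id)
  reps <- vector("list", nrow(rows))
  for (k in seq_len(nrow(rows))) {
    script <- do.call(motion_script,
                      c(list(angle_id = angle_id,
                             peaks = rows$executed_deg[k],
                             start_deg = rows$start_offset_deg[k]),
                        script_args))
    kin <- simulate_segment_kinematics(script, exam, catalog)
    streams <- list()
    for (site in names(kin$repetitions[[1]]$traces)) {
      m <- if (!is.null(mounting) && site %in% names(mounting))
        mounting[[site]] else c(1, 0, 0, 0)
      streams[[site]] <- synthesize_imu(
        kin$repetitions[[1]]$traces[[site]], noise, site_id = site,
        mounting = m,
        seed = .sub_seed(base_seed, rec_index * 101 + k * 13 +
                           match(site, .EXPECTED_SITES)))
    }
    reps[[k]] <- list(rep = rows$rep[k], streams = streams,
                      executed_deg = rows$executed_deg[k],
                      start_offset_deg = rows$start_offset_deg[k])
  }
  list(subject = rows$subject[1], rater = rows$rater[1], angle_id = angle_id,
       repetitions = reps)
}
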