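# Sensor-to-segment calibration at neutral posture, Grood-Suntay joint angle
# decomposition, the two measurement modes (two-sensor relative orientation,
# single sensor versus its start orientation), and min/max RoM extraction.
#
# Joint coordinate system convention (fixed package-wide, mirroring-by-sign
# handled in the catalog): in segment coordinates (x = sagittal/anterior,
# y = mediolateral/left, z = long axis) the flexion axis e1 is the proximal
# segment's y, the long axis e3 is the distal segment's z, and the floating
# abduction axis is their mutual perpendicular. With the canonical basis
# change below this is an intrinsic Cardan x-y'-z'' sequence, so
# compose-then-decompose round-trips exactly away from the |abduction| = 90
# degree singularity.

# canonical basis: columns are the JCS axes expressed in segment coordinates
# (x~ = flexion axis = y, y~ = floating at neutral = -x, z~ = long axis = z)
.JCS_C <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))

#' Decompose a relative orientation into Grood-Suntay joint angles
#'
#' Splits the proximal-frame-relative orientation of the distal segment into
#' the flexion (about the proximal flexion axis), abduction (floating axis;
#' deviation of the angle between flexion and long axes from 90 degrees),
#' and rotation (about the distal long axis) components.
#'
#' @param q_rel unit quaternion(s): distal segment frame expressed in the
#'   proximal (or start) segment frame; n x 4 matrix for a trace.
#' @return data.frame with columns `flexion`, `abduction`, `rotation`
#'   (degrees) and `gimbal` (TRUE when |abduction| > 80 degrees, where the
#'   flexion/rotation split degenerates; flagged, never an error).
#' @export
grood_suntay_decompose <- function(q_rel) {
  q <- .as_quat_mat(q_rel)
  n <- nrow(q)
  out <- data.frame(flexion = numeric(n), abduction = numeric(n),
                    rotation = numeric(n), gimbal = logical(n))
  Ct <- t(.JCS_C)
  for (i in seq_len(n)) {
    R <- Ct %*% quat_to_matrix(q[i, ]) %*% .JCS_C
    sb <- max(-1, min(1, R[1, 3]))
    out$flexion[i] <- atan2(-R[2, 3], R[3, 3]) * 180 / pi
    out$abduction[i] <- asin(sb) * 180 / pi
    out$rotation[i] <- atan2(-R[1, 2], R[1, 1]) * 180 / pi
    out$gimbal[i] <- abs(out$abduction[i]) > 80
  }
  out
}

#' Compose Grood-Suntay joint angles into a relative orientation
#'
#' Exact inverse of [grood_suntay_decompose()] away from the gimbal
#' singularity.
#'
#' @param flexion,abduction,rotation angles in degrees (vectorised).
#' @return unit quaternion(s).
#' @export
jcs_compose <- function(flexion, abduction, rotation) {
  n <- max(length(flexion), length(abduction), length(rotation))
  flexion <- rep_len(flexion, n) * pi / 180
  abduction <- rep_len(abduction, n) * pi / 180
  rotation <- rep_len(rotation, n) * pi / 180
  q <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    ca <- cos(flexion[i]); sa <- sin(flexion[i])
    cb <- cos(abduction[i]); sb <- sin(abduction[i])
    cg <- cos(rotation[i]); sg <- sin(rotation[i])
    Rx <- matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
    q[i, ] <- quat_from_matrix(.JCS_C %*% Rx %*% Ry %*% Rz %*% t(.JCS_C))
  }
  if (n == 1L) q[1L, ] else q
}

#' Neutral-posture sensor-to-segment calibration
#'
#' Simplified anatomical calibration from the defined neutral start posture:
#' over the initial static window the segment is assumed to stand exactly in
#' the catalog's neutral orientation; the sensor's inclination is measured
#' from gravity and its heading taken from the expected (protocol) sensor
#' orientation, i.e. the site's neutral axes composed with the prescribed
#' mounting. The result maps the estimated sensor orientation at
#' calibration time onto the neutral segment axes. A posture that deviates
#' from neutral cannot be detected by this procedure (inherent limitation of
#' the neutral-zero start); it shifts the resulting measurement.
#'
#' @param stream a `rom_imu_stream` whose first `init_window` seconds are
#'   static in the neutral posture.
#' @param site the `SensorSite` (for the neutral segment axes).
#' @param cfg a [filter_config()].
#' @param mounting prescribed sensor-to-segment mounting quaternion
#'   (protocol knowledge; identity if the sensor is mounted on the segment
#'   axes).
#' @return a `rom_calibration`: `site_id`, `q0` (initial sensor-to-world
#'   estimate), `q_sensor_to_segment` (right-multiply an estimated
#'   sensor-to-world quaternion with it to obtain segment-to-world),
#'   `residual_tilt` (degrees; within-window scatter of the measured gravity
#'   direction - a motion/quality metric), `timestamp_window`.
#' @export
calibrate_neutral <- function(stream, site, cfg = filter_config(),
                              mounting = c(1, 0, 0, 0)) {
  stopifnot(inherits(site, "rom_sensor_site"))
  q_neutral <- .site_neutral_quat(site)
  q_expected <- quat_multiply(q_neutral, quat_normalize(mounting))
  q0 <- init_orientation(stream, q_expected, cfg)  # errors if non-static
  idx <- which(stream$t - stream$t[1] < cfg$init_window - 1e-12)
  acc <- stream$accel[idx, , drop = FALSE]
  dirs <- acc / sqrt(rowSums(acc^2))
  mdir <- colMeans(dirs); mdir <- mdir / sqrt(sum(mdir^2))
  residual <- sqrt(mean(acos(pmin(1, pmax(-1, dirs %*% mdir)))^2)) * 180 / pi
  structure(list(site_id = site$site_id, q0 = q0,
                 q_sensor_to_segment = quat_normalize(
                   quat_multiply(quat_conjugate(q0), q_neutral)),
                 residual_tilt = residual,
                 timestamp_window = cfg$init_window),
            class = "rom_calibration")
}

#' Joint angle trace of one examination repetition
#'
#' Applies the examination's measurement mode and decomposes the relative
#' orientation into JCS components. In `two_imu_relative` mode the joint
#' rotation is the neutral-referenced orientation difference between the
#' proximal and distal segment estimates; in `single_imu_vs_start` mode it
#' is the orientation difference between the start and current orientation
#' of the distal sensor's segment.
#'
#' @param exam an `ExaminationAngle`.
#' @param traces named list `site_id -> rom_orientation_trace` of estimated
#'   *sensor*-to-world traces.
#' @param cal named list `site_id -> rom_calibration`.
#' @param catalog a `rom_catalog` (for neutral segment orientations).
#' @return a `rom_joint_angle_trace`: `angle_id`, `t`, and signed JCS
#'   components `flexion`, `abduction`, `rotation` (degrees) plus `gimbal`.
#' @export
joint_angle_trace <- function(exam, traces, cal, catalog) {
  need <- c(exam$distal_site,
            if (exam$method == "two_imu_relative") exam$proximal_site)
  for (s in need) {
    if (is.null(traces[[s]]))
      stop("configuration error: missing orientation trace for site '", s, "'")
    if (is.null(cal[[s]]))
      stop("configuration error: missing calibration for site '", s, "'")
  }
  seg <- lapply(need, function(s)
    quat_multiply(traces[[s]]$q, cal[[s]]$q_sensor_to_segment))
  names(seg) <- need
  qd <- seg[[exam$distal_site]]
  if (exam$method == "two_imu_relative") {
    qp <- seg[[exam$proximal_site]]
    q_np <- .site_neutral_quat(lookup_site(catalog, exam$proximal_site))
    q_nd <- .site_neutral_quat(lookup_site(catalog, exam$distal_site))
    # reference the relative orientation to its neutral value so the joint
    # angle is zero in the neutral start posture (neutral-zero convention)
    q_rel <- quat_multiply(
      quat_conjugate(quat_relative(q_np, q_nd)), quat_relative(qp, qd))
  } else {
    q_rel <- quat_relative(qd[1L, ], qd)
  }
  dec <- grood_suntay_decompose(q_rel)
  structure(list(angle_id = exam$angle_id, t = traces[[exam$distal_site]]$t,
                 flexion = dec$flexion, abduction = dec$abduction,
                 rotation = dec$rotation, gimbal = dec$gimbal),
            class = "rom_joint_angle_trace")
}

#' Extract the RoM result of one repetition
#'
#' Takes the minimum and maximum of the examination's JCS component over the
#' repetition and maps the extreme in the named direction to the anatomical
#' nomenclature: `sign = +1` reports the maximum, `sign = -1` the magnitude
#' of the minimum. Both extremes are retained so one recording can serve
#' paired left/right nomenclatures.
#'
#' @param trace a `rom_joint_angle_trace`.
#' @param exam the `ExaminationAngle`.
#' @param repetition repetition index stamped on the result.
#' @return a `rom_result`: `angle_id`, `repetition`, `min_deg`, `max_deg`
#'   (of the JCS component) and `reported_rom_deg`.
#' @export
extract_rom <- function(trace, exam, repetition = 1L) {
  stopifnot(inherits(trace, "rom_joint_angle_trace"))
  comp <- trace[[exam$jcs_axis]]
  if (length(comp) == 0L) stop("empty joint angle trace")
  mn <- min(comp); mx <- max(comp)
  reported <- if (exam$sign >= 0) mx else -mn
  structure(list(angle_id = exam$angle_id, repetition = repetition,
                 min_deg = mn, max_deg = mx, reported_rom_deg = reported),
            class = "rom_result")
}

#' Process one simulated recording into per-repetition RoM results
#'
#' Full measurement chain for one subject x rater x examination recording:
#' per repetition, neutral calibration over the initial static window,
#' magnetometer-free orientation estimation, joint angle decomposition and
#' min/max RoM extraction.
#'
#' @param recording one element of `simulate_study()$recordings` (fields
#'   `angle_id` and `repetitions`, each repetition holding `streams`).
#' @param catalog a `rom_catalog`.
#' @param cfg a [filter_config()].
#' @param mounting named list `site_id -> quaternion` of prescribed mounting
#'   offsets (protocol knowledge; `NULL` = identity).
#' @return data.frame: one row per repetition with `angle_id`, `rep`,
#'   `measured_rom_deg`, `min_deg`, `max_deg`, `residual_tilt_deg`.
#' @export
process_recording <- function(recording, catalog, cfg = filter_config(),
                              mounting = NULL) {
  exam <- lookup_examination(catalog, recording$angle_id)
  out <- NULL
  for (rep in recording$repetitions) {
    cal <- list(); traces <- list()
    for (s in names(rep$streams)) {
      m <- if (!is.null(mounting) && s %in% names(mounting))
        mounting[[s]] else c(1, 0, 0, 0)
      cal[[s]] <- calibrate_neutral(rep$streams[[s]],
                                    lookup_site(catalog, s), cfg, m)
      traces[[s]] <- estimate_orientation(rep$streams[[s]], cal[[s]]$q0, cfg)
    }
    jt <- joint_angle_trace(exam, traces, cal, catalog)
    rr <- extract_rom(jt, exam, repetition = rep$rep)
    out <- rbind(out, data.frame(
      angle_id = rr$angle_id, rep = rr$repetition,
      measured_rom_deg = rr$reported_rom_deg, min_deg = rr$min_deg,
      max_deg = rr$max_deg,
      residual_tilt_deg = max(vapply(cal, `[[`, 0, "residual_tilt"))))
  }
  out
}

#' Simulate and process a full study in one pass
#'
#' Convenience driver: draws the study design, then for every recording
#' synthesises the IMU streams, runs the measurement chain, and discards the
#' streams again, returning the measurement sheet next to the examiner sheet
#' and ground truth. Memory stays flat in the number of recordings.
#'
#' @inheritParams simulate_study
#' @param cfg a [filter_config()] for processing.
#' @return list `measurement_sheet` (subject, rater, angle_id, rep,
#'   measured_rom_deg, min_deg, max_deg), `examiner_sheet`, `truth`,
#'   `design`.
#' @export
run_study <- function(cohort, angle_ids, catalog = load_catalog(),
                      noise = noise_model(), mounting = NULL,
                      script_args = list(), cfg = filter_config()) {
  des <- simulate_design(cohort, angle_ids, catalog, noise)
  key <- unique(des$design[c("subject", "rater", "angle_id")])
  sheets <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    rows <- des$design[des$design$subject == key$subject[i] &
                         des$design$rater == key$rater[i] &
                         des$design$angle_id == key$angle_id[i], ]
    rec <- .simulate_recording(rows, key$angle_id[i], catalog, noise,
                               mounting, script_args,
                               base_seed = cohort$seed, rec_index = i)
    res <- process_recording(rec, catalog, cfg, mounting)
    res$subject <- key$subject[i]; res$rater <- key$rater[i]
    sheets[[i]] <- res
  }
  ms <- do.call(rbind, sheets)
  ms <- ms[c("subject", "rater", "angle_id", "rep", "measured_rom_deg",
             "min_deg", "max_deg")]
  list(measurement_sheet = ms,
       examiner_sheet = des$design[c("subject", "rater", "angle_id", "rep",
                                     "rating_deg")],
       truth = des$truth, design = des$design)
}
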