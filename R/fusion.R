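# Magnetometer-free orientation estimation.
#
# The estimator is a strapdown gyroscope integrator with a complementary,
# gravity-gated tilt correction. Initial inclination is taken from the
# gravity vector over a static window; the free heading is resolved from the
# expected segment orientation at the neutral start posture (the catalog's
# job), never from a magnetometer. Heading drift over a repetition is
# accepted: examinations last seconds and the system re-initialises at every
# repetition start.

.GRAVITY <- 9.81  # m/s^2, world +Z reaction on a resting accelerometer

#' Fusion filter configuration
#'
#' @param correction_gain per-sample blend weight of the gravity-based tilt
#'   correction, in `[0, 1]`. 0 disables correction (pure gyro integration).
#'   The default 0.02 at 100 Hz gives a tilt time constant of about 0.5 s.
#' @param accel_gate maximum deviation of the accelerometer norm from
#'   9.81 m/s^2 for a sample to be trusted as a gravity observation.
#' @param init_window length of the static averaging window used for
#'   initialisation/calibration at the start of each repetition, seconds.
#' @return a `rom_filter_config` list.
#' @export
filter_config <- function(correction_gain = 0.02, accel_gate = 0.5,
                          init_window = 1.0) {
  stopifnot(correction_gain >= 0, correction_gain <= 1, accel_gate > 0,
            init_window > 0)
  structure(list(correction_gain = correction_gain, accel_gate = accel_gate,
                 init_window = init_window), class = "rom_filter_config")
}

.check_stream <- function(stream) {
  stopifnot(inherits(stream, "rom_imu_stream"))
  n <- length(stream$t)
  if (n < 2L) stop("IMU stream must contain at least 2 samples")
  dt <- 1 / stream$sampling_rate
  if (max(abs(stream$t - (stream$t[1] + (seq_len(n) - 1) * dt))) > 1e-9)
    stop("IMU stream is not uniformly sampled at the stated rate")
  bad <- which(!is.finite(rowSums(stream$omega) + rowSums(stream$accel)))
  if (length(bad))
    stop("NaN/Inf in IMU stream at sample index ", bad[1])
  invisible(dt)
}

# accept either a full expected orientation quaternion or an expected
# world-frame heading vector for a sensor whose axes nominally match the
# world frame at neutral
.expected_quat <- function(expected) {
  if (length(expected) == 4L) return(quat_normalize(expected))
  if (length(expected) == 3L) {
    h <- c(expected[1], expected[2], 0)
    nh <- sqrt(sum(h^2))
    if (nh < 1e-9)
      stop("expected heading vector must have a horizontal component")
    x <- h / nh; z <- c(0, 0, 1)
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    return(quat_from_matrix(cbind(x, y, z)))
  }
  stop("expected orientation must be a quaternion (4) or heading vector (3)")
}

#' Initial orientation from a static window
#'
#' Estimates the sensor-to-world orientation at the start of a recording:
#' inclination is measured from the mean accelerometer direction over the
#' first `init_window` seconds (it must be gravity, hence the static
#' precondition), and the remaining free heading is taken from the expected
#' orientation of the sensor at the neutral start posture.
#'
#' @param stream a `rom_imu_stream` (see [imu_stream()]).
#' @param expected expected sensor orientation at neutral: a unit quaternion,
#'   or a world-frame heading vector for a sensor nominally aligned with the
#'   world axes.
#' @param cfg a [filter_config()].
#' @return a unit quaternion (sensor to world).
#' @export
init_orientation <- function(stream, expected, cfg = filter_config()) {
  .check_stream(stream)
  idx <- which(stream$t - stream$t[1] < cfg$init_window - 1e-12)
  if (length(idx) < 2L) stop("stream shorter than the initialisation window")
  abar <- colMeans(stream$accel[idx, , drop = FALSE])
  if (abs(sqrt(sum(abar^2)) - .GRAVITY) > cfg$accel_gate)
    stop("calibration error: start window is not quasi-static ",
         "(|mean accel| = ", round(sqrt(sum(abar^2)), 2),
         " m/s^2); repeat the neutral start posture")
  q_exp <- .expected_quat(expected)
  # world direction the expected orientation assigns to the measured accel
  up_meas <- quat_rotate(q_exp, abar / sqrt(sum(abar^2)))
  # minimal (tilt-only) world rotation re-aligning it with +Z
  q_fix <- quat_between(up_meas, c(0, 0, 1))
  quat_normalize(quat_multiply(q_fix, q_exp))
}

#' Estimate an orientation trace from an IMU stream
#'
#' Strapdown propagation by the quaternion exponential of `omega * dt`
#' with a gravity-gated complementary tilt correction. The correction rotates
#' the estimate about a horizontal axis only: heading is left untouched
#' (and is unobservable without a magnetometer).
#'
#' @param stream a `rom_imu_stream`.
#' @param q0 initial unit quaternion (sensor to world), e.g. from
#'   [init_orientation()].
#' @param cfg a [filter_config()].
#' @return an `OrientationTrace`: list with `t` (s) and `q` (n x 4 unit
#'   quaternions, sensor to world), class `rom_orientation_trace`.
#' @export
estimate_orientation <- function(stream, q0, cfg = filter_config()) {
  dt <- .check_stream(stream)
  q <- .strapdown_cpp(stream$omega, stream$accel, dt,
                      quat_normalize(q0), cfg$correction_gain,
                      cfg$accel_gate, .GRAVITY)
  orientation_trace(stream$t, q)
}

#' Construct an orientation trace
#' @param t sample times, seconds (uniform).
#' @param q n x 4 matrix of unit quaternions (sensor/segment to world).
#' @return a `rom_orientation_trace`.
#' @export
orientation_trace <- function(t, q) {
  q <- .as_quat_mat(q)
  stopifnot(length(t) == nrow(q))
  if (max(abs(sqrt(rowSums(q^2)) - 1)) > 1e-9)
    stop("orientation trace quaternions must be unit norm (tolerance 1e-9)")
  structure(list(t = as.numeric(t), q = .quat_continuous(q)),
            class = "rom_orientation_trace")
}

#' @export
print.rom_orientation_trace <- function(x, ...) {
  cat("OrientationTrace: ", length(x$t), " samples over ",
      round(diff(range(x$t)), 3), " s\n", sep = "")
  invisible(x)
}
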