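# Quaternion algebra used throughout the package.
#
# Conventions (fixed package-wide): Hamilton quaternions, scalar-first
# (w, x, y, z), passive sensor-to-world rotation: v_world = R(q) %*% v_body.
# World frame is right-handed with Z up; gravity points along -Z, so a
# resting accelerometer reports the gravitational reaction +Z.
#
# All functions are vectorised over rows: a "quaternion" argument is either a
# length-4 vector or an n x 4 matrix; 3-vectors likewise n x 3.

.as_quat_mat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  if (ncol(q) != 4L) stop("quaternion input must have 4 columns (w, x, y, z)")
  q
}

.as_vec3_mat <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(v) != 3L) stop("3-vector input must have 3 columns")
  v
}

.drop_quat <- function(q, was_vec) if (was_vec && nrow(q) == 1L) q[1L, ] else q

#' Quaternion product
#'
#' Hamilton product `a %*% b`, row-wise. Either argument may be a single
#' quaternion (length-4 vector), which is recycled against the other.
#'
#' @param a,b quaternions, length-4 vectors or n x 4 matrices (scalar first).
#' @return quaternion(s) with the shape of the larger argument.
#' @export
quat_multiply <- function(a, b) {
  va <- is.null(dim(a)); vb <- is.null(dim(b))
  a <- .as_quat_mat(a); b <- .as_quat_mat(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  .drop_quat(cbind(w, x, y, z, deparse.level = 0), va && vb)
}

#' Quaternion conjugate
#' @param q quaternion(s).
#' @return conjugate quaternion(s) (inverse for unit quaternions).
#' @export
quat_conjugate <- function(q) {
  v <- is.null(dim(q)); q <- .as_quat_mat(q)
  .drop_quat(cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4], deparse.level = 0), v)
}

#' Normalise quaternions to unit norm
#' @param q quaternion(s).
#' @return unit quaternion(s).
#' @export
quat_normalize <- function(q) {
  v <- is.null(dim(q)); q <- .as_quat_mat(q)
  n <- sqrt(rowSums(q^2))
  if (any(n < 1e-300)) stop("cannot normalise a zero quaternion")
  .drop_quat(q / n, v)
}

#' Relative orientation between two frames
#'
#' Returns `qa^-1 x qb`, the orientation of frame b expressed in frame a.
#' This is the elementary operation behind two-sensor joint angles.
#'
#' @param qa,qb unit quaternions (sensor/segment to world).
#' @return unit quaternion(s).
#' @export
quat_relative <- function(qa, qb) {
  quat_normalize(quat_multiply(quat_conjugate(qa), qb))
}

#' Axis-angle quaternion
#' @param axis unit 3-vector (or n x 3) rotation axis.
#' @param angle_rad rotation angle(s) in radians.
#' @return unit quaternion(s).
#' @export
quat_from_axis_angle <- function(axis, angle_rad) {
  axis <- .as_vec3_mat(axis)
  n <- max(nrow(axis), length(angle_rad))
  if (nrow(axis) == 1L && n > 1L) axis <- axis[rep(1L, n), , drop = FALSE]
  nrm <- sqrt(rowSums(axis^2))
  if (any(nrm < 1e-12)) stop("rotation axis must be non-zero")
  axis <- axis / nrm
  h <- angle_rad / 2
  q <- cbind(cos(h), sin(h) * axis[, 1], sin(h) * axis[, 2], sin(h) * axis[, 3],
             deparse.level = 0)
  if (n == 1L) q[1L, ] else q
}

#' Rotate vectors by quaternions
#' @param q unit quaternion(s), sensor-to-world.
#' @param v 3-vector(s) in the source frame.
#' @return rotated 3-vector(s) in the target frame.
#' @export
quat_rotate <- function(q, v) {
  vq <- is.null(dim(q)) && is.null(dim(v))
  q <- .as_quat_mat(q); v <- .as_vec3_mat(v)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v), u = vector part
  ux <- q[, 2]; uy <- q[, 3]; uz <- q[, 4]; w <- q[, 1]
  cx <- uy * v[, 3] - uz * v[, 2]
  cy <- uz * v[, 1] - ux * v[, 3]
  cz <- ux * v[, 2] - uy * v[, 1]
  c2x <- uy * cz - uz * cy
  c2y <- uz * cx - ux * cz
  c2z <- ux * cy - uy * cx
  out <- cbind(v[, 1] + 2 * (w * cx + c2x),
               v[, 2] + 2 * (w * cy + c2y),
               v[, 3] + 2 * (w * cz + c2z), deparse.level = 0)
  if (vq && n == 1L) out[1L, ] else out
}

#' Rotation matrix of a unit quaternion
#' @param q a single unit quaternion.
#' @return 3 x 3 rotation matrix mapping body to world coordinates.
#' @export
quat_to_matrix <- function(q) {
  q <- .as_quat_mat(q)
  if (nrow(q) != 1L) stop("quat_to_matrix expects a single quaternion")
  w <- q[1, 1]; x <- q[1, 2]; y <- q[1, 3]; z <- q[1, 4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion from a rotation matrix
#' @param R 3 x 3 rotation matrix (body to world).
#' @return unit quaternion, positive scalar part.
#' @export
quat_from_matrix <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Rotation-vector logarithm of unit quaternions
#'
#' Returns the rotation vector (axis times angle, radians) such that
#' `quat_from_rotvec(quat_to_rotvec(q))` reproduces `q` up to sign.
#'
#' @param q unit quaternion(s).
#' @return n x 3 matrix (or 3-vector) of rotation vectors.
#' @export
quat_to_rotvec <- function(q) {
  v <- is.null(dim(q)); q <- .as_quat_mat(q)
  # force w >= 0 for the short arc
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  vn <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, q[, 1])
  scale <- ifelse(vn > 1e-12, ang / vn, 2 / pmax(q[, 1], 1e-12))
  out <- q[, 2:4, drop = FALSE] * scale
  if (v) out[1L, ] else out
}

#' Quaternion exponential of rotation vectors
#' @param rv rotation vector(s), axis times angle in radians.
#' @return unit quaternion(s).
#' @export
quat_from_rotvec <- function(rv) {
  v <- is.null(dim(rv)); rv <- .as_vec3_mat(rv)
  ang <- sqrt(rowSums(rv^2))
  half <- ang / 2
  # sinc form is stable at small angles
  s <- ifelse(ang > 1e-12, sin(half) / ang, 0.5 - ang^2 / 48)
  q <- cbind(cos(half), rv[, 1] * s, rv[, 2] * s, rv[, 3] * s,
             deparse.level = 0)
  if (v) q[1L, ] else q
}

#' Geodesic angle between orientations
#'
#' Smallest rotation angle taking one orientation into the other, in degrees.
#'
#' @param qa,qb unit quaternion(s).
#' @return angle(s) in degrees, in [0, 180].
#' @export
quat_angle_deg <- function(qa, qb) {
  d <- quat_multiply(quat_conjugate(qa), qb)
  d <- .as_quat_mat(d)
  2 * atan2(sqrt(rowSums(d[, 2:4, drop = FALSE]^2)), abs(d[, 1])) * 180 / pi
}

#' Minimal rotation between two directions
#'
#' Quaternion of the smallest rotation taking direction `u` onto direction
#' `v`, optionally scaled to a fraction of that rotation (used by the
#' complementary tilt correction).
#'
#' @param u,v 3-vectors (not necessarily unit).
#' @param fraction fraction of the full rotation to apply, in [0, 1].
#' @return a single unit quaternion.
#' @export
quat_between <- function(u, v, fraction = 1) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(c(1, 0, 0, 0))
    # antipodal: pick any perpendicular axis
    ax <- if (abs(u[1]) < 0.9) c(0, -u[3], u[2]) else c(-u[2], u[1], 0)
    ax <- ax / sqrt(sum(ax^2))
    return(quat_from_axis_angle(ax, pi * fraction))
  }
  quat_from_axis_angle(ax / s, atan2(s, c_) * fraction)
}

# enforce a sign-continuous quaternion trajectory (no antipodal flips)
.quat_continuous <- function(q) {
  if (nrow(q) < 2L) return(q)
  d <- rowSums(q[-1L, , drop = FALSE] * q[-nrow(q), , drop = FALSE])
  flip <- cumprod(ifelse(d < 0, -1, 1))
  q[-1L, ] <- q[-1L, , drop = FALSE] * flip
  q
}
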