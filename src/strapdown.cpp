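#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Strapdown integration with complementary gravity-based tilt correction.
//
// Conventions match the R side: Hamilton quaternions, scalar first, passive
// sensor->world. Propagation uses the quaternion exponential of omega*dt
// (exact for a constant rate over one step). When the accelerometer norm is
// within `accel_gate` of 9.81 m/s^2 the estimate is rotated toward the
// orientation re-aligning the measured specific force with world +Z by the
// fraction `gain`; the correction axis is horizontal by construction, so the
// (magnetometer-free, unobservable) heading is never touched.

static inline void qmul(const double *a, const double *b, double *out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

static inline void qnormalize(double *q) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int i = 0; i < 4; ++i) q[i] /= n;
}

// rotate body vector v by q (body -> world)
static inline void qrot(const double *q, const double *v, double *out) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double cx = y*v[2] - z*v[1];
  double cy = z*v[0] - x*v[2];
  double cz = x*v[1] - y*v[0];
  out[0] = v[0] + 2.0*(w*cx + y*cz - z*cy);
  out[1] = v[1] + 2.0*(w*cy + z*cx - x*cz);
  out[2] = v[2] + 2.0*(w*cz + x*cy - y*cx);
}

// [[Rcpp::export(name = ".strapdown_cpp")]]
NumericMatrix strapdown_cpp(NumericMatrix omega, NumericMatrix accel,
                            double dt, NumericVector q0, double gain,
                            double accel_gate, double gravity) {
  const int n = omega.nrow();
  if (accel.nrow() != n) stop("omega and accel must have equal length");
  NumericMatrix out(n, 4);
  double q[4] = { q0[0], q0[1], q0[2], q0[3] };
  qnormalize(q);
  for (int j = 0; j < 4; ++j) out(0, j) = q[j];

  for (int k = 1; k < n; ++k) {
    // propagate with the rate measured over the previous interval
    double wx = omega(k - 1, 0), wy = omega(k - 1, 1), wz = omega(k - 1, 2);
    if (!std::isfinite(wx) || !std::isfinite(wy) || !std::isfinite(wz))
      stop("NaN/Inf in angular-rate stream at sample %d", k);
    double ang = std::sqrt(wx*wx + wy*wy + wz*wz) * dt;
    double dq[4];
    if (ang > 1e-14) {
      double h = ang / 2.0, s = std::sin(h) * dt / ang; // sin(|w|dt/2)/|w|
      dq[0] = std::cos(h);
      dq[1] = wx * s; dq[2] = wy * s; dq[3] = wz * s;
    } else {
      dq[0] = 1.0; dq[1] = wx * dt / 2.0; dq[2] = wy * dt / 2.0;
      dq[3] = wz * dt / 2.0;
    }
    double qn[4];
    qmul(q, dq, qn);
    for (int j = 0; j < 4; ++j) q[j] = qn[j];
    qnormalize(q);

    // gravity-gated complementary tilt correction
    double ax = accel(k, 0), ay = accel(k, 1), az = accel(k, 2);
    if (!std::isfinite(ax) || !std::isfinite(ay) || !std::isfinite(az))
      stop("NaN/Inf in acceleration stream at sample %d", k);
    if (gain > 0.0) {
      double anorm = std::sqrt(ax*ax + ay*ay + az*az);
      if (std::fabs(anorm - gravity) <= accel_gate && anorm > 1e-9) {
        double ab[3] = { ax / anorm, ay / anorm, az / anorm };
        double aw[3];
        qrot(q, ab, aw); // measured "up" in world frame
        // minimal rotation from aw to +Z, scaled by gain
        double cx = aw[1], cy = -aw[0];   // aw x z
        double s = std::sqrt(cx*cx + cy*cy);
        if (s > 1e-12) {
          double phi = std::atan2(s, aw[2]) * gain;
          double h = phi / 2.0, sh = std::sin(h) / s;
          double cq[4] = { std::cos(h), cx * sh, cy * sh, 0.0 };
          double qc[4];
          qmul(cq, q, qc);
          for (int j = 0; j < 4; ++j) q[j] = qc[j];
          qnormalize(q);
        }
      }
    }
    // keep a sign-continuous trajectory
    double dot = 0.0;
    for (int j = 0; j < 4; ++j) dot += q[j] * out(k - 1, j);
    if (dot < 0.0) for (int j = 0; j < 4; ++j) q[j] = -q[j];
    for (int j = 0; j < 4; ++j) out(k, j) = q[j];
  }
  return out;
}
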