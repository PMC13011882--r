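#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Magnetostatic field of a uniformly polarized cuboid, body frame, polarization
// J (tesla) along +z, half-edges a,b,c.  Charged-surface closed form: the two
// faces perpendicular to z carry surface charge +/- J.  Returns mu0*H; the
// caller adds J inside the volume to obtain B.
static inline void cuboid_axial_H(double x, double y, double z,
                                  double a, double b, double c,
                                  double J, double out[3]) {
  const double u[2] = {x + a, x - a};
  const double v[2] = {y + b, y - b};
  const double w[2] = {z + c, z - c};
  const double u2[2] = {u[0] * u[0], u[1] * u[1]};
  const double v2[2] = {v[0] * v[0], v[1] * v[1]};
  const double w2[2] = {w[0] * w[0], w[1] * w[1]};
  // fuse the 16 logarithms into 2 via log(prod(+terms)/prod(-terms))
  double numx = 1.0, denx = 1.0, numy = 1.0, deny = 1.0, bz = 0.0;
  for (int i = 0; i < 2; ++i) {
    for (int j = 0; j < 2; ++j) {
      for (int k = 0; k < 2; ++k) {
        const double r = std::sqrt(u2[i] + v2[j] + w2[k]);
        const double tx = v[j] + r, ty = u[i] + r;
        const double at = std::atan(u[i] * v[j] / (w[k] * r));
        if ((i + j + k) & 1) {
          denx *= tx; deny *= ty; bz += at;
        } else {
          numx *= tx; numy *= ty; bz -= at;
        }
      }
    }
  }
  const double f = J / (4.0 * M_PI);
  out[0] = f * std::log(numx / denx);
  out[1] = f * std::log(numy / deny);
  out[2] = f * bz;
}

// Superposed field of many cuboid magnets at many points.
//   centers : M x 3 (m), world frame
//   half    : M half edge lengths (m)
//   rot     : M x 9 rotation matrices, row-major, body -> world
//   Jbody   : M x 3 polarization vectors in the body frame (tesla)
//   points  : P x 3 (m), world frame
// Returns P x 3 matrix of B (tesla).
// [[Rcpp::export]]
NumericMatrix cpp_field_cuboids(NumericMatrix centers, NumericVector half,
                                NumericMatrix rot, NumericMatrix Jbody,
                                NumericMatrix points) {
  const int M = centers.nrow(), P = points.nrow();
  NumericMatrix B(P, 3);
  std::vector<double> px(P), py(P), pz(P);
  for (int p = 0; p < P; ++p) {
    px[p] = points(p, 0); py[p] = points(p, 1); pz[p] = points(p, 2);
  }
  double tmp[3];
  for (int m = 0; m < M; ++m) {
    const double cx = centers(m, 0), cy = centers(m, 1), cz = centers(m, 2);
    const double h = half[m];
    double R[9];
    for (int t = 0; t < 9; ++t) R[t] = rot(m, t);
    const double Jx = Jbody(m, 0), Jy = Jbody(m, 1), Jz = Jbody(m, 2);
    for (int p = 0; p < P; ++p) {
      const double dx = px[p] - cx, dy = py[p] - cy, dz = pz[p] - cz;
      // body coordinates: q = R^T d
      const double qx = R[0] * dx + R[3] * dy + R[6] * dz;
      const double qy = R[1] * dx + R[4] * dy + R[7] * dz;
      const double qz = R[2] * dx + R[5] * dy + R[8] * dz;
      double Hb0 = 0.0, Hb1 = 0.0, Hb2 = 0.0;
      if (Jx != 0.0) {  // polarization along body x: permuted frame (y,z,x)
        cuboid_axial_H(qy, qz, qx, h, h, h, Jx, tmp);
        Hb0 += tmp[2]; Hb1 += tmp[0]; Hb2 += tmp[1];
      }
      if (Jy != 0.0) {  // along body y: permuted frame (z,x,y)
        cuboid_axial_H(qz, qx, qy, h, h, h, Jy, tmp);
        Hb0 += tmp[1]; Hb1 += tmp[2]; Hb2 += tmp[0];
      }
      if (Jz != 0.0) {
        cuboid_axial_H(qx, qy, qz, h, h, h, Jz, tmp);
        Hb0 += tmp[0]; Hb1 += tmp[1]; Hb2 += tmp[2];
      }
      if (std::fabs(qx) < h && std::fabs(qy) < h && std::fabs(qz) < h) {
        Hb0 += Jx; Hb1 += Jy; Hb2 += Jz;
      }
      // back to world frame: B += R * Hb
      B(p, 0) += R[0] * Hb0 + R[1] * Hb1 + R[2] * Hb2;
      B(p, 1) += R[3] * Hb0 + R[4] * Hb1 + R[5] * Hb2;
      B(p, 2) += R[6] * Hb0 + R[7] * Hb1 + R[8] * Hb2;
    }
  }
  return B;
}
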