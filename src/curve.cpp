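// Tangent-stepping reconstruction of a curve centerline from its intrinsic
// geometry (start point, initial tangent, Fourier curvature model).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler steps: x(t+dt) = x(t) + dt T(t); T(t+dt) = T(t) + N(t) K(t/L) dt,
// N = (-Ty, Tx, 0) (pi/2 rotation of the tangent within the XY plane).
// T is renormalized after each step so t remains an arc-length parameter.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_curve(NumericVector origin, NumericVector tangent,
                                    double k0, double w, NumericVector p,
                                    NumericVector q, double L, int n_steps) {
  const int N = p.size();
  const double ds = L / n_steps;
  NumericMatrix pts(n_steps + 1, 3);
  double x[3] = {origin[0], origin[1], origin[2]};
  double T[3] = {tangent[0], tangent[1], tangent[2]};
  pts(0, 0) = x[0]; pts(0, 1) = x[1]; pts(0, 2) = x[2];
  for (int s = 0; s < n_steps; ++s) {
    const double t = (double)s * ds / L;  // normalized arc length in [0,1)
    double K = k0;
    for (int i = 1; i <= N; ++i) {
      K += p[i - 1] * std::cos(i * w * t) + q[i - 1] * std::sin(i * w * t);
    }
    const double nx = -T[1], ny = T[0];  // in-plane normal, zero Z
    x[0] += ds * T[0]; x[1] += ds * T[1]; x[2] += ds * T[2];
    T[0] += nx * K * ds;
    T[1] += ny * K * ds;
    const double nrm = std::sqrt(T[0] * T[0] + T[1] * T[1] + T[2] * T[2]);
    T[0] /= nrm; T[1] /= nrm; T[2] /= nrm;
    pts(s + 1, 0) = x[0]; pts(s + 1, 1) = x[1]; pts(s + 1, 2) = x[2];
  }
  return pts;
}
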