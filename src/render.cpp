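// Gaussian feature render kernels and analytic Jacobians.
//
// All positions are physical (micron) coordinates; voxel (i,j,k) (0-based)
// has its center at ((i+0.5)dx, (j+0.5)dy, (k+0.5)dz). Arrays are returned
// as flat vectors in R column-major order: index = i + nx*(j + ny*k).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SQRT_PI = 1.7724538509055160273;

// Spot: f(x) = A exp(-((x-cx)/sx)^2 - ((y-cy)/sy)^2 - ((z-cz)/sz)^2)
// Jacobian columns: A, cx, cy, cz, sx, sy, sz
// [[Rcpp::export]]
List cpp_spot_render(IntegerVector dim, NumericVector vox,
                     double A, NumericVector center, NumericVector sigma,
                     bool grad = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector val(n);
  NumericMatrix jac = grad ? NumericMatrix(n, 7) : NumericMatrix(0, 0);

  std::vector<double> dx(nx), dy(ny), dz(nz);
  for (int i = 0; i < nx; ++i) dx[i] = (i + 0.5) * vox[0] - center[0];
  for (int j = 0; j < ny; ++j) dy[j] = (j + 0.5) * vox[1] - center[1];
  for (int k = 0; k < nz; ++k) dz[k] = (k + 0.5) * vox[2] - center[2];
  const double ivx = 1.0 / (sigma[0] * sigma[0]),
               ivy = 1.0 / (sigma[1] * sigma[1]),
               ivz = 1.0 / (sigma[2] * sigma[2]);
  std::vector<double> ex(nx), ey(ny), ez(nz);
  for (int i = 0; i < nx; ++i) ex[i] = std::exp(-dx[i] * dx[i] * ivx);
  for (int j = 0; j < ny; ++j) ey[j] = std::exp(-dy[j] * dy[j] * ivy);
  for (int k = 0; k < nz; ++k) ez[k] = std::exp(-dz[k] * dz[k] * ivz);

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const double eyz = ey[j] * ez[k];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double e = ex[i] * eyz;
        const double f = A * e;
        val[idx] = f;
        if (grad) {
          jac(idx, 0) = e;
          jac(idx, 1) = f * 2.0 * dx[i] * ivx;
          jac(idx, 2) = f * 2.0 * dy[j] * ivy;
          jac(idx, 3) = f * 2.0 * dz[k] * ivz;
          jac(idx, 4) = f * 2.0 * dx[i] * dx[i] * ivx / sigma[0];
          jac(idx, 5) = f * 2.0 * dy[j] * dy[j] * ivy / sigma[1];
          jac(idx, 6) = f * 2.0 * dz[k] * dz[k] * ivz / sigma[2];
        }
      }
    }
  if (grad) return List::create(_["values"] = val, _["jac"] = jac);
  return List::create(_["values"] = val);
}

// Line: closed-form (error function) evaluation of
//   f(x) = Int_0^1 A exp(-sum_a ((x_a - p0_a - u_a t)/sigma_a)^2) dt
// With alpha = sum u_a^2/s_a^2, beta = sum d_a u_a/s_a^2,
// gamma = sum d_a^2/s_a^2 (d = x - p0, u = p1 - p0):
//   f = A (sqrt(pi)/(2 sqrt(alpha))) exp(beta^2/alpha - gamma)
//       [erf(sqrt(alpha) - beta/sqrt(alpha)) - erf(-beta/sqrt(alpha))]
// Jacobian columns: A, p0x, p0y, p0z, p1x, p1y, p1z, sx, sy, sz
// [[Rcpp::export]]
List cpp_line_render_erf(IntegerVector dim, NumericVector vox,
                         double A, NumericVector p0, NumericVector p1,
                         NumericVector sigma, bool grad = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector val(n);
  NumericMatrix jac = grad ? NumericMatrix(n, 10) : NumericMatrix(0, 0);

  const double iv[3] = {1.0 / (sigma[0] * sigma[0]),
                        1.0 / (sigma[1] * sigma[1]),
                        1.0 / (sigma[2] * sigma[2])};
  const double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  const double alpha = u[0] * u[0] * iv[0] + u[1] * u[1] * iv[1] +
                       u[2] * u[2] * iv[2];

  if (alpha < 1e-14) {
    // Degenerate line (start == end): integrand is constant in t, so the
    // render equals a spot at the midpoint. Position gradients split
    // equally between the two coincident endpoints.
    NumericVector mid = NumericVector::create(
        0.5 * (p0[0] + p1[0]), 0.5 * (p0[1] + p1[1]), 0.5 * (p0[2] + p1[2]));
    List sp = cpp_spot_render(dim, vox, A, mid, sigma, grad);
    if (!grad) return sp;
    NumericMatrix sj = sp["jac"];
    for (R_xlen_t r = 0; r < n; ++r) {
      jac(r, 0) = sj(r, 0);
      for (int a = 0; a < 3; ++a) {
        jac(r, 1 + a) = 0.5 * sj(r, 1 + a);
        jac(r, 4 + a) = 0.5 * sj(r, 1 + a);
        jac(r, 7 + a) = sj(r, 4 + a);
      }
    }
    return List::create(_["values"] = sp["values"], _["jac"] = jac);
  }

  const double sqa = std::sqrt(alpha);
  std::vector<double> dxv(nx), dyv(ny), dzv(nz);
  for (int i = 0; i < nx; ++i) dxv[i] = (i + 0.5) * vox[0] - p0[0];
  for (int j = 0; j < ny; ++j) dyv[j] = (j + 0.5) * vox[1] - p0[1];
  for (int k = 0; k < nz; ++k) dzv[k] = (k + 0.5) * vox[2] - p0[2];

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double bz = dzv[k] * u[2] * iv[2];
    const double gz = dzv[k] * dzv[k] * iv[2];
    for (int j = 0; j < ny; ++j) {
      const double byz = bz + dyv[j] * u[1] * iv[1];
      const double gyz = gz + dyv[j] * dyv[j] * iv[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double d[3] = {dxv[i], dyv[j], dzv[k]};
        const double beta = byz + d[0] * u[0] * iv[0];
        const double gamma = gyz + d[0] * d[0] * iv[0];
        const double P = 0.5 * SQRT_PI / sqa *
                         std::exp(beta * beta / alpha - gamma);
        const double s1 = sqa - beta / sqa, s0 = -beta / sqa;
        const double W = std::erf(s1) - std::erf(s0);
        const double F = A * P * W;
        val[idx] = F;
        if (!grad) continue;

        const double E1 = std::exp(-s1 * s1), E0 = std::exp(-s0 * s0);
        const double dFdb =
            A * P * (2.0 * beta / alpha * W -
                     2.0 / (SQRT_PI * sqa) * (E1 - E0));
        const double dFdg = -F;
        const double dFda =
            A * (P * (-0.5 / alpha - beta * beta / (alpha * alpha)) * W +
                 P * (2.0 / SQRT_PI) *
                     (E1 * (0.5 / sqa + beta / (2.0 * alpha * sqa)) -
                      E0 * (beta / (2.0 * alpha * sqa))));
        jac(idx, 0) = P * W;
        for (int a = 0; a < 3; ++a) {
          jac(idx, 1 + a) = dFda * (-2.0 * u[a] * iv[a]) +
                            dFdb * (-(u[a] + d[a]) * iv[a]) +
                            dFdg * (-2.0 * d[a] * iv[a]);
          jac(idx, 4 + a) = dFda * (2.0 * u[a] * iv[a]) +
                            dFdb * (d[a] * iv[a]);
          jac(idx, 7 + a) = (dFda * (-2.0 * u[a] * u[a]) +
                             dFdb * (-2.0 * d[a] * u[a]) +
                             dFdg * (-2.0 * d[a] * d[a])) *
                            iv[a] / sigma[a];
        }
      }
    }
  }
  if (grad) return List::create(_["values"] = val, _["jac"] = jac);
  return List::create(_["values"] = val);
}

// Subset variants: evaluate value (and optionally the Jacobian) only at the
// voxels given by 0-based flat indices `idx` (column-major, i + nx*(j+ny*k)).
// Used to fit on regions of interest / informative-voxel masks.

// [[Rcpp::export]]
List cpp_spot_render_idx(IntegerVector dim, NumericVector vox,
                         double A, NumericVector center, NumericVector sigma,
                         IntegerVector idx, bool grad = false) {
  const int nx = dim[0], ny = dim[1];
  const R_xlen_t m = idx.size();
  NumericVector val(m);
  NumericMatrix jac = grad ? NumericMatrix(m, 7) : NumericMatrix(0, 0);
  const double iv[3] = {1.0 / (sigma[0] * sigma[0]),
                        1.0 / (sigma[1] * sigma[1]),
                        1.0 / (sigma[2] * sigma[2])};
  for (R_xlen_t r = 0; r < m; ++r) {
    const int flat = idx[r];
    const int i = flat % nx, j = (flat / nx) % ny, k = flat / (nx * ny);
    const double d[3] = {(i + 0.5) * vox[0] - center[0],
                         (j + 0.5) * vox[1] - center[1],
                         (k + 0.5) * vox[2] - center[2]};
    const double e = std::exp(-(d[0] * d[0] * iv[0] + d[1] * d[1] * iv[1] +
                                d[2] * d[2] * iv[2]));
    const double f = A * e;
    val[r] = f;
    if (grad) {
      jac(r, 0) = e;
      for (int a = 0; a < 3; ++a) {
        jac(r, 1 + a) = f * 2.0 * d[a] * iv[a];
        jac(r, 4 + a) = f * 2.0 * d[a] * d[a] * iv[a] / sigma[a];
      }
    }
  }
  if (grad) return List::create(_["values"] = val, _["jac"] = jac);
  return List::create(_["values"] = val);
}

// [[Rcpp::export]]
List cpp_line_render_erf_idx(IntegerVector dim, NumericVector vox,
                             double A, NumericVector p0, NumericVector p1,
                             NumericVector sigma, IntegerVector idx,
                             bool grad = false) {
  const int nx = dim[0], ny = dim[1];
  const R_xlen_t m = idx.size();
  const double iv[3] = {1.0 / (sigma[0] * sigma[0]),
                        1.0 / (sigma[1] * sigma[1]),
                        1.0 / (sigma[2] * sigma[2])};
  const double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  const double alpha = u[0] * u[0] * iv[0] + u[1] * u[1] * iv[1] +
                       u[2] * u[2] * iv[2];
  NumericVector val(m);
  NumericMatrix jac = grad ? NumericMatrix(m, 10) : NumericMatrix(0, 0);

  if (alpha < 1e-14) {
    NumericVector mid = NumericVector::create(
        0.5 * (p0[0] + p1[0]), 0.5 * (p0[1] + p1[1]), 0.5 * (p0[2] + p1[2]));
    List sp = cpp_spot_render_idx(dim, vox, A, mid, sigma, idx, grad);
    if (!grad) return sp;
    NumericMatrix sj = sp["jac"];
    for (R_xlen_t r = 0; r < m; ++r) {
      jac(r, 0) = sj(r, 0);
      for (int a = 0; a < 3; ++a) {
        jac(r, 1 + a) = 0.5 * sj(r, 1 + a);
        jac(r, 4 + a) = 0.5 * sj(r, 1 + a);
        jac(r, 7 + a) = sj(r, 4 + a);
      }
    }
    return List::create(_["values"] = sp["values"], _["jac"] = jac);
  }

  const double sqa = std::sqrt(alpha);
  for (R_xlen_t r = 0; r < m; ++r) {
    const int flat = idx[r];
    const int i = flat % nx, j = (flat / nx) % ny, k = flat / (nx * ny);
    const double d[3] = {(i + 0.5) * vox[0] - p0[0],
                         (j + 0.5) * vox[1] - p0[1],
                         (k + 0.5) * vox[2] - p0[2]};
    const double beta = d[0] * u[0] * iv[0] + d[1] * u[1] * iv[1] +
                        d[2] * u[2] * iv[2];
    const double gamma = d[0] * d[0] * iv[0] + d[1] * d[1] * iv[1] +
                         d[2] * d[2] * iv[2];
    const double P = 0.5 * SQRT_PI / sqa *
                     std::exp(beta * beta / alpha - gamma);
    const double s1 = sqa - beta / sqa, s0 = -beta / sqa;
    const double W = std::erf(s1) - std::erf(s0);
    const double F = A * P * W;
    val[r] = F;
    if (!grad) continue;
    const double E1 = std::exp(-s1 * s1), E0 = std::exp(-s0 * s0);
    const double dFdb = A * P * (2.0 * beta / alpha * W -
                                 2.0 / (SQRT_PI * sqa) * (E1 - E0));
    const double dFdg = -F;
    const double dFda =
        A * (P * (-0.5 / alpha - beta * beta / (alpha * alpha)) * W +
             P * (2.0 / SQRT_PI) *
                 (E1 * (0.5 / sqa + beta / (2.0 * alpha * sqa)) -
                  E0 * (beta / (2.0 * alpha * sqa))));
    jac(r, 0) = P * W;
    for (int a = 0; a < 3; ++a) {
      jac(r, 1 + a) = dFda * (-2.0 * u[a] * iv[a]) +
                      dFdb * (-(u[a] + d[a]) * iv[a]) +
                      dFdg * (-2.0 * d[a] * iv[a]);
      jac(r, 4 + a) = dFda * (2.0 * u[a] * iv[a]) + dFdb * (d[a] * iv[a]);
      jac(r, 7 + a) = (dFda * (-2.0 * u[a] * u[a]) +
                       dFdb * (-2.0 * d[a] * u[a]) +
                       dFdg * (-2.0 * d[a] * d[a])) * iv[a] / sigma[a];
    }
  }
  if (grad) return List::create(_["values"] = val, _["jac"] = jac);
  return List::create(_["values"] = val);
}

// Quadrature render: f(x) = A sum_q w_q exp(-sum_a ((x_a - P_qa)/s_a)^2).
// Used for numeric line integration and for curved centerlines. Each node
// only touches voxels within `cut` standard deviations (negligible beyond).
// [[Rcpp::export]]
NumericVector cpp_gauss_sum_render(IntegerVector dim, NumericVector vox,
                                   double A, NumericMatrix pts,
                                   NumericVector w, NumericVector sigma,
                                   double cut = 6.0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector val(n);
  const double iv[3] = {1.0 / (sigma[0] * sigma[0]),
                        1.0 / (sigma[1] * sigma[1]),
                        1.0 / (sigma[2] * sigma[2])};
  const int m = pts.nrow();
  for (int q = 0; q < m; ++q) {
    const double cx = pts(q, 0), cy = pts(q, 1), cz = pts(q, 2);
    const double wq = A * w[q];
    const int i0 = std::max(0, (int)std::floor((cx - cut * sigma[0]) / vox[0] - 0.5));
    const int i1 = std::min(nx - 1, (int)std::ceil((cx + cut * sigma[0]) / vox[0] - 0.5));
    const int j0 = std::max(0, (int)std::floor((cy - cut * sigma[1]) / vox[1] - 0.5));
    const int j1 = std::min(ny - 1, (int)std::ceil((cy + cut * sigma[1]) / vox[1] - 0.5));
    const int k0 = std::max(0, (int)std::floor((cz - cut * sigma[2]) / vox[2] - 0.5));
    const int k1 = std::min(nz - 1, (int)std::ceil((cz + cut * sigma[2]) / vox[2] - 0.5));
    for (int k = k0; k <= k1; ++k) {
      const double dz = (k + 0.5) * vox[2] - cz;
      const double gz = dz * dz * iv[2];
      for (int j = j0; j <= j1; ++j) {
        const double dy = (j + 0.5) * vox[1] - cy;
        const double gyz = gz + dy * dy * iv[1];
        R_xlen_t idx = i0 + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i, ++idx) {
          const double dx = (i + 0.5) * vox[0] - cx;
          val[idx] += wq * std::exp(-(gyz + dx * dx * iv[0]));
        }
      }
    }
  }
  return val;
}
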