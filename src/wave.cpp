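// Explicit elastodynamic solvers on the regular output grid.
//
// Default engine: scalar SH-like equation for the vertical displacement
// u(x, y, t),   rho u_tt = d/dx(mu u_x) + d/dy(mu u_y) + f,
// the standard acoustoelastic reading of shear waves generated by a
// full-depth vertical push in a nearly incompressible 2D medium.
// Heterogeneous mu (tangent modulus mapped from the pre-strained state),
// mu = 0 outside the domain (free surface), Dirichlet u = 0 on clamped
// cells (base), no damping.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_wave_sh(NumericMatrix mu, LogicalMatrix fixed, double rho,
                          double hx, double dt, int nsub, int nrec,
                          NumericVector fbody, double push_dur) {
  const int nx = mu.nrow(), ny = mu.ncol();
  std::vector<double> u0(nx * ny, 0.0), u1(nx * ny, 0.0), u2(nx * ny, 0.0);
  NumericVector rec((R_xlen_t)nrec * nx * ny);
  const double inv_h2 = 1.0 / (hx * hx);
  const double dt2_rho = dt * dt / rho;
  auto IDX = [nx](int i, int j) { return i + (R_xlen_t)nx * j; };
  // face coefficients (arithmetic mean, zero outside domain)
  std::vector<double> cE(nx * ny, 0.0), cW(nx * ny, 0.0), cN(nx * ny, 0.0),
      cS(nx * ny, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const double mc = mu(i, j);
      if (mc <= 0.0) continue;
      cE[IDX(i, j)] = (i + 1 < nx && mu(i + 1, j) > 0)
                          ? 0.5 * (mc + mu(i + 1, j)) : 0.0;
      cW[IDX(i, j)] = (i > 0 && mu(i - 1, j) > 0)
                          ? 0.5 * (mc + mu(i - 1, j)) : 0.0;
      cN[IDX(i, j)] = (j + 1 < ny && mu(i, j + 1) > 0)
                          ? 0.5 * (mc + mu(i, j + 1)) : 0.0;
      cS[IDX(i, j)] = (j > 0 && mu(i, j - 1) > 0)
                          ? 0.5 * (mc + mu(i, j - 1)) : 0.0;
    }
  double t = 0.0;
  R_xlen_t rk = 0;
  // frame 0 is the zero initial state
  for (R_xlen_t q = 0; q < (R_xlen_t)nx * ny; ++q) rec[rk++] = 0.0;
  for (int frame = 1; frame < nrec; ++frame) {
    for (int s = 0; s < nsub; ++s) {
      const bool pushing = (t < push_dur);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t q = IDX(i, j);
          if (mu(i, j) <= 0.0 || fixed(i, j)) { u2[q] = 0.0; continue; }
          const double lap =
              (cE[q] * ((i + 1 < nx ? u1[IDX(i + 1, j)] : 0.0) - u1[q]) -
               cW[q] * (u1[q] - (i > 0 ? u1[IDX(i - 1, j)] : 0.0)) +
               cN[q] * ((j + 1 < ny ? u1[IDX(i, j + 1)] : 0.0) - u1[q]) -
               cS[q] * (u1[q] - (j > 0 ? u1[IDX(i, j - 1)] : 0.0))) *
              inv_h2;
          double acc = lap;
          if (pushing) acc += fbody[q];
          u2[q] = 2.0 * u1[q] - u0[q] + dt2_rho * acc;
        }
      std::swap(u0, u1);
      std::swap(u1, u2);
      t += dt;
    }
    for (R_xlen_t q = 0; q < (R_xlen_t)nx * ny; ++q) rec[rk++] = u1[q];
    Rcpp::checkUserInterrupt();
  }
  rec.attr("dim") = IntegerVector::create(nx, ny, nrec);
  return rec;
}

// Vector P-SV engine (validation flag): displacement-form leapfrog for
// isotropic heterogeneous (lambda, mu), body force on u_y only.
// [[Rcpp::export]]
NumericVector cpp_wave_psv(NumericMatrix mu, NumericMatrix lam,
                           LogicalMatrix fixed, double rho, double hx,
                           double dt, int nsub, int nrec, NumericVector fbody,
                           double push_dur) {
  const int nx = mu.nrow(), ny = mu.ncol();
  const R_xlen_t N = (R_xlen_t)nx * ny;
  std::vector<double> ux0(N, 0), ux1(N, 0), ux2(N, 0), uy0(N, 0), uy1(N, 0),
      uy2(N, 0);
  NumericVector rec((R_xlen_t)nrec * nx * ny);
  auto IDX = [nx](int i, int j) { return i + (R_xlen_t)nx * j; };
  auto IN = [&](int i, int j) {
    return i >= 0 && i < nx && j >= 0 && j < ny && mu(i, j) > 0.0;
  };
  const double inv_h = 1.0 / hx, dt2_rho = dt * dt / rho;
  double t = 0.0;
  R_xlen_t rk = 0;
  for (R_xlen_t q = 0; q < N; ++q) rec[rk++] = 0.0;
  // stress at cell faces via centered differences; traction-free faces
  // handled by zero moduli outside
  std::vector<double> sxx(N), syy(N), sxy(N);
  for (int frame = 1; frame < nrec; ++frame) {
    for (int s = 0; s < nsub; ++s) {
      const bool pushing = (t < push_dur);
      // cell-centered stresses from one-sided/centered gradients
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t q = IDX(i, j);
          if (mu(i, j) <= 0.0) { sxx[q] = syy[q] = sxy[q] = 0.0; continue; }
          const double uxE = IN(i + 1, j) ? ux1[IDX(i + 1, j)] : ux1[q];
          const double uxW = IN(i - 1, j) ? ux1[IDX(i - 1, j)] : ux1[q];
          const double uxN = IN(i, j + 1) ? ux1[IDX(i, j + 1)] : ux1[q];
          const double uxS = IN(i, j - 1) ? ux1[IDX(i, j - 1)] : ux1[q];
          const double uyE = IN(i + 1, j) ? uy1[IDX(i + 1, j)] : uy1[q];
          const double uyW = IN(i - 1, j) ? uy1[IDX(i - 1, j)] : uy1[q];
          const double uyN = IN(i, j + 1) ? uy1[IDX(i, j + 1)] : uy1[q];
          const double uyS = IN(i, j - 1) ? uy1[IDX(i, j - 1)] : uy1[q];
          const double exx = 0.5 * (uxE - uxW) * inv_h;
          const double eyy = 0.5 * (uyN - uyS) * inv_h;
          const double exy = 0.25 * ((uxN - uxS) + (uyE - uyW)) * inv_h;
          const double tr = exx + eyy;
          sxx[q] = lam(i, j) * tr + 2.0 * mu(i, j) * exx;
          syy[q] = lam(i, j) * tr + 2.0 * mu(i, j) * eyy;
          sxy[q] = 2.0 * mu(i, j) * exy;
        }
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t q = IDX(i, j);
          if (mu(i, j) <= 0.0 || fixed(i, j)) { ux2[q] = uy2[q] = 0.0; continue; }
          const double sxxE = IN(i + 1, j) ? sxx[IDX(i + 1, j)] : 0.0;
          const double sxxW = IN(i - 1, j) ? sxx[IDX(i - 1, j)] : 0.0;
          const double syyN = IN(i, j + 1) ? syy[IDX(i, j + 1)] : 0.0;
          const double syyS = IN(i, j - 1) ? syy[IDX(i, j - 1)] : 0.0;
          const double sxyE = IN(i + 1, j) ? sxy[IDX(i + 1, j)] : 0.0;
          const double sxyW = IN(i - 1, j) ? sxy[IDX(i - 1, j)] : 0.0;
          const double sxyN = IN(i, j + 1) ? sxy[IDX(i, j + 1)] : 0.0;
          const double sxyS = IN(i, j - 1) ? sxy[IDX(i, j - 1)] : 0.0;
          double ax = 0.5 * ((sxxE - sxxW) + (sxyN - sxyS)) * inv_h;
          double ay = 0.5 * ((sxyE - sxyW) + (syyN - syyS)) * inv_h;
          if (pushing) ay += fbody[q];
          ux2[q] = 2.0 * ux1[q] - ux0[q] + dt2_rho * ax;
          uy2[q] = 2.0 * uy1[q] - uy0[q] + dt2_rho * ay;
        }
      std::swap(ux0, ux1); std::swap(ux1, ux2);
      std::swap(uy0, uy1); std::swap(uy1, uy2);
      t += dt;
    }
    for (R_xlen_t q = 0; q < N; ++q) rec[rk++] = uy1[q];
    Rcpp::checkUserInterrupt();
  }
  rec.attr("dim") = IntegerVector::create(nx, ny, nrec);
  return rec;
}
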