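#ifndef NLSWEI_MATERIAL_H
#define NLSWEI_MATERIAL_H

#include <cmath>
#include <stdexcept>

// Second-order polynomial hyperelastic solid (Mooney-Rivlin family),
// plane strain: in-plane F is 2x2, out-of-plane stretch = 1.
// Coefficients in Pa (c*) and 1/Pa (d*).  When `iso` is set the
// deviatoric invariants I1b = J^{-2/3} I1, I2b = J^{-4/3} I2 enter the
// polynomial and the volume response is carried by the d-terms alone.
struct Mat {
  double c10, c01, c11, c20, c02, d1, d2;
  bool iso;
};

// F stored column-major: F[0]=F11, F[1]=F21, F[2]=F12, F[3]=F22.
inline double det2(const double *F) { return F[0] * F[3] - F[1] * F[2]; }

inline double strain_energy_F(const Mat &m, const double *F) {
  const double J = det2(F);
  if (!(J > 0.0)) throw std::runtime_error("degenerate deformation: J <= 0");
  // left Cauchy-Green B = F F^T (3D, B33 = 1)
  const double B11 = F[0] * F[0] + F[2] * F[2];
  const double B22 = F[1] * F[1] + F[3] * F[3];
  const double B12 = F[0] * F[1] + F[2] * F[3];
  double i1 = B11 + B22 + 1.0;
  // I2 = sum of principal 2x2 minors; with B33 = 1, B13 = B23 = 0
  double i2 = (B11 * B22 - B12 * B12) + B11 + B22;
  if (m.iso) {
    const double j23 = std::pow(J, -2.0 / 3.0);
    i1 *= j23;
    i2 *= j23 * j23;
  }
  const double a = i1 - 3.0, b = i2 - 3.0, v = J - 1.0;
  return m.c10 * a + m.c01 * b + m.c11 * a * b + m.c20 * a * a +
         m.c02 * b * b + v * v / m.d1 + v * v * v * v / m.d2;
}

// deviatoric / volumetric split used by the selective-integration element
inline double strain_energy_split(const Mat &m, const double *F, bool vol) {
  const double J = det2(F);
  if (!(J > 0.0)) throw std::runtime_error("degenerate deformation: J <= 0");
  if (vol) {
    const double v = J - 1.0;
    return v * v / m.d1 + v * v * v * v / m.d2;
  }
  const double B11 = F[0] * F[0] + F[2] * F[2];
  const double B22 = F[1] * F[1] + F[3] * F[3];
  const double B12 = F[0] * F[1] + F[2] * F[3];
  double i1 = B11 + B22 + 1.0;
  double i2 = (B11 * B22 - B12 * B12) + B11 + B22;
  if (m.iso) {
    const double j23 = std::pow(J, -2.0 / 3.0);
    i1 *= j23;
    i2 *= j23 * j23;
  }
  const double a = i1 - 3.0, b = i2 - 3.0;
  return m.c10 * a + m.c01 * b + m.c11 * a * b + m.c20 * a * a + m.c02 * b * b;
}

// first Piola-Kirchhoff stress dU/dF by central differences (h on F ~ O(1))
template <int MODE>  // 0 full, 1 deviatoric only, 2 volumetric only
inline void pk1_fd(const Mat &m, const double *F, double *P, double h = 1e-7) {
  double Fp[4];
  for (int k = 0; k < 4; ++k) {
    for (int q = 0; q < 4; ++q) Fp[q] = F[q];
    Fp[k] = F[k] + h;
    double up = (MODE == 0) ? strain_energy_F(m, Fp)
                            : strain_energy_split(m, Fp, MODE == 2);
    Fp[k] = F[k] - h;
    double um = (MODE == 0) ? strain_energy_F(m, Fp)
                            : strain_energy_split(m, Fp, MODE == 2);
    P[k] = (up - um) / (2.0 * h);
  }
}

// Cauchy stress sigma = P F^T / J (in-plane 2x2) plus out-of-plane s33
inline void cauchy_from_F(const Mat &m, const double *F, double *sig,
                          double *s33) {
  double P[4];
  pk1_fd<0>(m, F, P);
  const double J = det2(F);
  sig[0] = (P[0] * F[0] + P[2] * F[2]) / J;             // s11
  sig[1] = (P[1] * F[0] + P[3] * F[2]) / J;             // s21
  sig[2] = (P[0] * F[1] + P[2] * F[3]) / J;             // s12
  sig[3] = (P[1] * F[1] + P[3] * F[3]) / J;             // s22
  if (s33) {
    // dU/dF33 at F33 = 1 via central difference on the 3D energy;
    // only J and the invariants change through F33 = lambda3
    const double h = 1e-7;
    auto u3 = [&](double l3) {
      const double J2 = det2(F);
      const double B11 = F[0] * F[0] + F[2] * F[2];
      const double B22 = F[1] * F[1] + F[3] * F[3];
      const double B12 = F[0] * F[1] + F[2] * F[3];
      double i1 = B11 + B22 + l3 * l3;
      double i2 = (B11 * B22 - B12 * B12) + (B11 + B22) * l3 * l3;
      const double J = J2 * l3;
      if (m.iso) {
        const double j23 = std::pow(J, -2.0 / 3.0);
        i1 *= j23;
        i2 *= j23 * j23;
      }
      const double a = i1 - 3.0, b = i2 - 3.0, v = J - 1.0;
      return m.c10 * a + m.c01 * b + m.c11 * a * b + m.c20 * a * a +
             m.c02 * b * b + v * v / m.d1 + v * v * v * v / m.d2;
    };
    *s33 = (u3(1.0 + h) - u3(1.0 - h)) / (2.0 * h) / det2(F);
  }
}

// Tangent (wave-carrying) shear modulus at pre-strain F for a shear
// increment du_y/dx = gamma, i.e. F' = (I + gamma e2 (x) e1) F.
// mode 0: acoustoelastic, (1/J) d2U/dgamma2  (acoustic-tensor A2121)
// mode 1: slope of Cauchy shear stress, d sigma21 / d gamma
inline double tangent_shear_F(const Mat &m, const double *F, double gamma,
                              int mode) {
  double Fp[4], Fm[4];
  // (I + g e2 e1) F: adds g * row1 of F into row2
  Fp[0] = F[0]; Fp[2] = F[2];
  Fm[0] = F[0]; Fm[2] = F[2];
  Fp[1] = F[1] + gamma * F[0]; Fp[3] = F[3] + gamma * F[2];
  Fm[1] = F[1] - gamma * F[0]; Fm[3] = F[3] - gamma * F[2];
  if (mode == 0) {
    const double u0 = strain_energy_F(m, F);
    const double up = strain_energy_F(m, Fp);
    const double um = strain_energy_F(m, Fm);
    return (up + um - 2.0 * u0) / (gamma * gamma) / det2(F);
  }
  double sp[4], sm[4];
  cauchy_from_F(m, Fp, sp, nullptr);
  cauchy_from_F(m, Fm, sm, nullptr);
  return (sp[1] - sm[1]) / (2.0 * gamma);
}

#endif
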