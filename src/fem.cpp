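// Plane-strain total-Lagrangian Q4 element with selective reduced
// integration: deviatoric energy at 2x2 Gauss points, volumetric penalty
// at the centroid (guards against volumetric locking at nu = 0.495).
#include <Rcpp.h>
#include "material.h"
using namespace Rcpp;

static const double GP = 0.5773502691896258;  // 1/sqrt(3)

struct ElemGeom {
  // shape gradients dN/dX (4 nodes x 2 dims) and weight w*detJ per point
  double dNdX[5][4][2];
  double wdet[5];
};

static void shape_grad(const double *Xe, double xi, double eta, double g[4][2],
                       double *wdet, double w) {
  // Q4 shape derivative wrt (xi, eta); nodes ccw: (-1,-1),(1,-1),(1,1),(-1,1)
  const double dxi[4] = {-(1 - eta) / 4, (1 - eta) / 4, (1 + eta) / 4,
                         -(1 + eta) / 4};
  const double det_[4] = {-(1 - xi) / 4, -(1 + xi) / 4, (1 + xi) / 4,
                          (1 - xi) / 4};
  double J11 = 0, J12 = 0, J21 = 0, J22 = 0;  // dX/dxi
  for (int a = 0; a < 4; ++a) {
    J11 += Xe[a] * dxi[a];       // x coords in Xe[0..3], y in Xe[4..7]
    J21 += Xe[4 + a] * dxi[a];
    J12 += Xe[a] * det_[a];
    J22 += Xe[4 + a] * det_[a];
  }
  const double det = J11 * J22 - J12 * J21;
  const double i11 = J22 / det, i12 = -J12 / det, i21 = -J21 / det,
               i22 = J11 / det;
  for (int a = 0; a < 4; ++a) {
    g[a][0] = dxi[a] * i11 + det_[a] * i21;
    g[a][1] = dxi[a] * i12 + det_[a] * i22;
  }
  *wdet = w * det;
}

static void elem_geom(const double *Xe, ElemGeom &eg) {
  const double pts[5][3] = {{-GP, -GP, 1}, {GP, -GP, 1}, {GP, GP, 1},
                            {-GP, GP, 1},  {0, 0, 4}};
  for (int p = 0; p < 5; ++p)
    shape_grad(Xe, pts[p][0], pts[p][1], eg.dNdX[p], &eg.wdet[p], pts[p][2]);
}

// internal force of one element; ue = (ux0..ux3, uy0..uy3)
static void elem_force(const ElemGeom &eg, const Mat &m, const double *ue,
                       double *fe) {
  for (int k = 0; k < 8; ++k) fe[k] = 0.0;
  double F[4], P[4];
  for (int p = 0; p < 5; ++p) {
    // F = I + sum_a u_a (x) dNa/dX
    F[0] = 1; F[1] = 0; F[2] = 0; F[3] = 1;
    for (int a = 0; a < 4; ++a) {
      F[0] += ue[a] * eg.dNdX[p][a][0];
      F[2] += ue[a] * eg.dNdX[p][a][1];
      F[1] += ue[4 + a] * eg.dNdX[p][a][0];
      F[3] += ue[4 + a] * eg.dNdX[p][a][1];
    }
    if (p < 4)
      pk1_fd<1>(m, F, P);  // deviatoric at 2x2 points
    else
      pk1_fd<2>(m, F, P);  // volumetric at centroid
    const double w = eg.wdet[p];
    for (int a = 0; a < 4; ++a) {
      fe[a]     += w * (P[0] * eg.dNdX[p][a][0] + P[2] * eg.dNdX[p][a][1]);
      fe[4 + a] += w * (P[1] * eg.dNdX[p][a][0] + P[3] * eg.dNdX[p][a][1]);
    }
  }
}

static Mat mat_from_row(const NumericMatrix &mats, int r) {
  Mat m;
  m.c10 = mats(r, 0); m.c01 = mats(r, 1); m.c11 = mats(r, 2);
  m.c20 = mats(r, 3); m.c02 = mats(r, 4); m.d1 = mats(r, 5);
  m.d2 = mats(r, 6); m.iso = mats(r, 7) != 0.0;
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_fem_force(NumericMatrix X, IntegerMatrix elems,
                            IntegerVector emat, NumericMatrix mats,
                            NumericVector u) {
  const int ne = elems.nrow(), n = X.nrow();
  NumericVector f(2 * n);
  double Xe[8], ue[8], fe[8];
  ElemGeom eg;
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a);
      Xe[a] = X(nd, 0); Xe[4 + a] = X(nd, 1);
      ue[a] = u[2 * nd]; ue[4 + a] = u[2 * nd + 1];
    }
    elem_geom(Xe, eg);
    const Mat m = mat_from_row(mats, emat[e]);
    elem_force(eg, m, ue, fe);
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a);
      f[2 * nd] += fe[a];
      f[2 * nd + 1] += fe[4 + a];
    }
  }
  return f;
}

// global stiffness triplets by central differences of the element force
// [[Rcpp::export]]
List cpp_fem_stiffness(NumericMatrix X, IntegerMatrix elems,
                       IntegerVector emat, NumericMatrix mats,
                       NumericVector u, double h) {
  const int ne = elems.nrow();
  IntegerVector ti(ne * 64), tj(ne * 64);
  NumericVector tv(ne * 64);
  double Xe[8], ue[8], fp[8], fm[8];
  ElemGeom eg;
  int dof[8];
  R_xlen_t k = 0;
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a);
      Xe[a] = X(nd, 0); Xe[4 + a] = X(nd, 1);
      ue[a] = u[2 * nd]; ue[4 + a] = u[2 * nd + 1];
      dof[a] = 2 * nd; dof[4 + a] = 2 * nd + 1;
    }
    elem_geom(Xe, eg);
    const Mat m = mat_from_row(mats, emat[e]);
    for (int c = 0; c < 8; ++c) {
      const double keep = ue[c];
      ue[c] = keep + h;
      elem_force(eg, m, ue, fp);
      ue[c] = keep - h;
      elem_force(eg, m, ue, fm);
      ue[c] = keep;
      for (int r = 0; r < 8; ++r) {
        ti[k] = dof[r];
        tj[k] = dof[c];
        tv[k] = (fp[r] - fm[r]) / (2.0 * h);
        ++k;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["v"] = tv);
}

// per-element centroid deformation gradient, Cauchy stress, tangent shear
// modulus and energy, for DeformedState fields
// [[Rcpp::export]]
List cpp_fem_fields(NumericMatrix X, IntegerMatrix elems, IntegerVector emat,
                    NumericMatrix mats, NumericVector u, double gamma,
                    int tangent_mode) {
  const int ne = elems.nrow();
  NumericMatrix Fc(ne, 4), sig(ne, 4);
  NumericVector s33(ne), gt(ne), en(ne);
  double Xe[8], ue[8];
  ElemGeom eg;
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a);
      Xe[a] = X(nd, 0); Xe[4 + a] = X(nd, 1);
      ue[a] = u[2 * nd]; ue[4 + a] = u[2 * nd + 1];
    }
    elem_geom(Xe, eg);
    double F[4] = {1, 0, 0, 1};
    for (int a = 0; a < 4; ++a) {  // centroid point index 4
      F[0] += ue[a] * eg.dNdX[4][a][0];
      F[2] += ue[a] * eg.dNdX[4][a][1];
      F[1] += ue[4 + a] * eg.dNdX[4][a][0];
      F[3] += ue[4 + a] * eg.dNdX[4][a][1];
    }
    const Mat m = mat_from_row(mats, emat[e]);
    double s[4], z33;
    cauchy_from_F(m, F, s, &z33);
    for (int q = 0; q < 4; ++q) {
      Fc(e, q) = F[q];
      sig(e, q) = s[q];
    }
    s33[e] = z33;
    gt[e] = tangent_shear_F(m, F, gamma, tangent_mode);
    en[e] = strain_energy_F(m, F);
  }
  return List::create(_["F"] = Fc, _["stress"] = sig, _["s33"] = s33,
                      _["tangent"] = gt, _["energy"] = en);
}

// total stored energy (same quadrature as the force)
// [[Rcpp::export]]
double cpp_fem_energy(NumericMatrix X, IntegerMatrix elems, IntegerVector emat,
                      NumericMatrix mats, NumericVector u) {
  const int ne = elems.nrow();
  double Xe[8], ue[8], F[4];
  ElemGeom eg;
  double tot = 0.0;
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a) {
      const int nd = elems(e, a);
      Xe[a] = X(nd, 0); Xe[4 + a] = X(nd, 1);
      ue[a] = u[2 * nd]; ue[4 + a] = u[2 * nd + 1];
    }
    elem_geom(Xe, eg);
    const Mat m = mat_from_row(mats, emat[e]);
    for (int p = 0; p < 5; ++p) {
      F[0] = 1; F[1] = 0; F[2] = 0; F[3] = 1;
      for (int a = 0; a < 4; ++a) {
        F[0] += ue[a] * eg.dNdX[p][a][0];
        F[2] += ue[a] * eg.dNdX[p][a][1];
        F[1] += ue[4 + a] * eg.dNdX[p][a][0];
        F[3] += ue[4 + a] * eg.dNdX[p][a][1];
      }
      tot += eg.wdet[p] * strain_energy_split(m, F, p == 4);
    }
  }
  return tot;
}
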