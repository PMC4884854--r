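#include <Rcpp.h>
#include "material.h"
using namespace Rcpp;

static Mat mat_from_vec(const NumericVector &p) {
  Mat m;
  m.c10 = p["c10"]; m.c01 = p["c01"]; m.c11 = p["c11"];
  m.c20 = p["c20"]; m.c02 = p["c02"]; m.d1 = p["d1"]; m.d2 = p["d2"];
  m.iso = p["iso"] != 0.0;
  return m;
}

// [[Rcpp::export]]
double cpp_strain_energy_F(NumericVector par, NumericMatrix F) {
  const Mat m = mat_from_vec(par);
  const double Fv[4] = {F(0, 0), F(1, 0), F(0, 1), F(1, 1)};
  return strain_energy_F(m, Fv);
}

// [[Rcpp::export]]
List cpp_cauchy_F(NumericVector par, NumericMatrix F) {
  const Mat m = mat_from_vec(par);
  const double Fv[4] = {F(0, 0), F(1, 0), F(0, 1), F(1, 1)};
  double s[4], s33;
  cauchy_from_F(m, Fv, s, &s33);
  NumericMatrix sig(2, 2);
  sig(0, 0) = s[0]; sig(1, 0) = s[1]; sig(0, 1) = s[2]; sig(1, 1) = s[3];
  return List::create(_["sigma"] = sig, _["s33"] = s33);
}

// [[Rcpp::export]]
double cpp_tangent_shear(NumericVector par, NumericMatrix F, double gamma,
                         int mode) {
  const Mat m = mat_from_vec(par);
  const double Fv[4] = {F(0, 0), F(1, 0), F(0, 1), F(1, 1)};
  return tangent_shear_F(m, Fv, gamma, mode);
}
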