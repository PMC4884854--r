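// Rasterize per-element fields of the (possibly deformed) FE mesh onto a
// regular grid: each deformed quadrilateral paints grid points inside it.
#include <Rcpp.h>
using namespace Rcpp;

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

static bool in_tri(double px, double py, double x0, double y0, double x1,
                   double y1, double x2, double y2, double eps) {
  const double d0 = cross2(x1 - x0, y1 - y0, px - x0, py - y0);
  const double d1 = cross2(x2 - x1, y2 - y1, px - x1, py - y1);
  const double d2 = cross2(x0 - x2, y0 - y2, px - x2, py - y2);
  const bool neg = (d0 < -eps) || (d1 < -eps) || (d2 < -eps);
  const bool pos = (d0 > eps) || (d1 > eps) || (d2 > eps);
  return !(neg && pos);
}

// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix XY, IntegerMatrix elems, NumericVector val,
                   IntegerVector lab, double x0, double y0, double h, int nx,
                   int ny) {
  NumericMatrix out(nx, ny);
  IntegerMatrix olab(nx, ny);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::fill(olab.begin(), olab.end(), NA_INTEGER);
  const int ne = elems.nrow();
  const double eps = 1e-9 * h * h;
  for (int e = 0; e < ne; ++e) {
    double qx[4], qy[4];
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
    for (int a = 0; a < 4; ++a) {
      qx[a] = XY(elems(e, a), 0);
      qy[a] = XY(elems(e, a), 1);
      xmin = std::min(xmin, qx[a]); xmax = std::max(xmax, qx[a]);
      ymin = std::min(ymin, qy[a]); ymax = std::max(ymax, qy[a]);
    }
    const int i0 = std::max(0, (int)std::ceil((xmin - x0) / h - 1e-9));
    const int i1 = std::min(nx - 1, (int)std::floor((xmax - x0) / h + 1e-9));
    const int j0 = std::max(0, (int)std::ceil((ymin - y0) / h - 1e-9));
    const int j1 = std::min(ny - 1, (int)std::floor((ymax - y0) / h + 1e-9));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        const double px = x0 + i * h, py = y0 + j * h;
        if (in_tri(px, py, qx[0], qy[0], qx[1], qy[1], qx[2], qy[2], eps) ||
            in_tri(px, py, qx[0], qy[0], qx[2], qy[2], qx[3], qy[3], eps)) {
          out(i, j) = val[e];
          olab(i, j) = lab[e];
        }
      }
  }
  return List::create(_["value"] = out, _["label"] = olab);
}
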