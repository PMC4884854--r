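// Reconstruction kernels: arrival-time picking, NA-aware depth averaging,
// sliding-window position-vs-time slope fits, 2D median filter.
#include <Rcpp.h>
using namespace Rcpp;

// peak |u| arrival per (x, y) column with 3-point parabolic refinement.
// rec has dim (nt, nx, ny); returns arrival time (s), NA where the peak
// amplitude is below `rel_thresh` times the global peak.
// [[Rcpp::export]]
NumericMatrix cpp_peak_arrival(NumericVector rec, double dt, double rel_thresh,
                               bool refine, int k0, int k1) {
  IntegerVector d = rec.attr("dim");
  const int nt = d[0], nx = d[1], ny = d[2];
  k0 = std::max(0, k0);
  k1 = std::min(nt - 1, k1 < 0 ? nt - 1 : k1);
  NumericMatrix arr(nx, ny);
  double gmax = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)nt * (i + (R_xlen_t)nx * j);
      for (int k = k0; k <= k1; ++k)
        gmax = std::max(gmax, std::fabs(rec[base + k]));
    }
  const double thr = rel_thresh * gmax;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)nt * (i + (R_xlen_t)nx * j);
      int kbest = -1;
      double vbest = 0.0;
      for (int k = k0; k <= k1; ++k) {
        const double v = std::fabs(rec[base + k]);
        if (v > vbest) { vbest = v; kbest = k; }
      }
      if (kbest < 0 || vbest < thr) { arr(i, j) = NA_REAL; continue; }
      double tk = kbest;
      if (refine && kbest > 0 && kbest < nt - 1) {
        const double a = std::fabs(rec[base + kbest - 1]);
        const double b = vbest;
        const double c = std::fabs(rec[base + kbest + 1]);
        const double den = a - 2.0 * b + c;
        if (std::fabs(den) > 1e-300) {
          double off = 0.5 * (a - c) / den;
          if (off > -0.5 && off < 0.5) tk += off;
        }
      }
      arr(i, j) = tk * dt;
    }
  return arr;
}

// Causality-constrained (front-tracking) arrival picking: marching away
// from the push, the search window for column i is
// [arr(i-1) - slack, arr(i-1) + dx/vmin], which keeps the picker locked
// to the outgoing front and immune to late multipath energy
// (base/surface reverberation that still travels forward in x and can
// exceed the direct pulse far from the push).  Columns before `istart`
// are NA; the first column is picked in [k0, t(istart)/vmin_start].
// pick = 0: time of the window |u| peak (parabolic-refined);
// pick = 1: leading edge, first sample above `edge_frac` of the window
// peak, linearly interpolated.
// [[Rcpp::export]]
NumericMatrix cpp_front_arrival(NumericVector rec, double dt, double dx,
                                double rel_thresh, bool refine, int k0,
                                int k1, int istart, double x0, double vmin,
                                int slack, int pick, double edge_frac) {
  IntegerVector d = rec.attr("dim");
  const int nt = d[0], nx = d[1], ny = d[2];
  k0 = std::max(0, k0);
  k1 = std::min(nt - 1, k1 < 0 ? nt - 1 : k1);
  NumericMatrix arr(nx, ny);
  std::fill(arr.begin(), arr.end(), NA_REAL);
  if (istart < 0 || istart >= nx) return arr;
  double gmax = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = istart; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)nt * (i + (R_xlen_t)nx * j);
      for (int k = k0; k <= k1; ++k)
        gmax = std::max(gmax, std::fabs(rec[base + k]));
    }
  const double thr = rel_thresh * gmax;
  const int grow = std::max(1, (int)std::ceil(dx / (vmin * dt)));
  for (int j = 0; j < ny; ++j) {
    // first column: bounded by travel at vmin from the push
    int lo = k0,
        hi = std::min(k1, (int)std::ceil(x0 / (vmin * dt)) + k0 + 2 * grow);
    for (int i = istart; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)nt * (i + (R_xlen_t)nx * j);
      int kbest = -1;
      double vbest = 0.0;
      for (int k = lo; k <= hi; ++k) {
        const double v = std::fabs(rec[base + k]);
        if (v > vbest) { vbest = v; kbest = k; }
      }
      if (kbest < 0 || vbest < thr) {
        // keep a growing window anchored at the last lock
        hi = std::min(k1, hi + grow);
        continue;
      }
      double tk = kbest;
      if (pick == 1) {
        // leading edge: first sample in the window above edge_frac * peak
        const double lev = edge_frac * vbest;
        int ke = kbest;
        while (ke > lo && std::fabs(rec[base + ke - 1]) >= lev) --ke;
        tk = ke;
        if (ke > 0) {
          const double va = std::fabs(rec[base + ke - 1]);
          const double vb = std::fabs(rec[base + ke]);
          if (vb > va) tk = ke - (vb - lev) / (vb - va);
        }
      } else if (refine && kbest > 0 && kbest < nt - 1) {
        const double a = std::fabs(rec[base + kbest - 1]);
        const double b = vbest;
        const double c = std::fabs(rec[base + kbest + 1]);
        const double den = a - 2.0 * b + c;
        if (std::fabs(den) > 1e-300) {
          const double off = 0.5 * (a - c) / den;
          if (off > -0.5 && off < 0.5) tk += off;
        }
      }
      arr(i, j) = tk * dt;
      lo = std::max(k0, kbest - slack);
      hi = std::min(k1, kbest + grow + slack);
    }
  }
  return arr;
}

// centered moving average across depth (columns of the nx-by-ny matrix),
// requiring at least min_n finite values
// [[Rcpp::export]]
NumericMatrix cpp_movmean_y(NumericMatrix m, int hw, int min_n) {
  const int nx = m.nrow(), ny = m.ncol();
  NumericMatrix out(nx, ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      double s = 0.0;
      int n = 0;
      for (int k = std::max(0, j - hw); k <= std::min(ny - 1, j + hw); ++k)
        if (R_finite(m(i, k))) { s += m(i, k); ++n; }
      out(i, j) = (n >= min_n) ? s / n : NA_REAL;
    }
  return out;
}

// sliding-window least-squares slope of lateral position x against
// arrival time t; speed = dx/dt.  Windows are centered, half-width hw
// samples; fits with fewer than min_n finite arrivals, non-positive or
// out-of-range speeds are masked.
// [[Rcpp::export]]
NumericMatrix cpp_tof_slope(NumericMatrix arr, double dx, int hw, int min_n,
                            double vmin, double vmax) {
  const int nx = arr.nrow(), ny = arr.ncol();
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double st = 0, sx = 0, stt = 0, stx = 0;
      int n = 0;
      for (int k = std::max(0, i - hw); k <= std::min(nx - 1, i + hw); ++k) {
        const double t = arr(k, j);
        if (!R_finite(t)) continue;
        const double x = k * dx;
        st += t; sx += x; stt += t * t; stx += t * x;
        ++n;
      }
      if (n < min_n) { out(i, j) = NA_REAL; continue; }
      const double den = n * stt - st * st;
      if (den <= 0.0) { out(i, j) = NA_REAL; continue; }
      const double v = (n * stx - st * sx) / den;
      out(i, j) = (v >= vmin && v <= vmax) ? v : NA_REAL;
    }
  return out;
}

// 2D median filter with NA handling (median of finite values in the
// centered window; NA when fewer than min_n)
// [[Rcpp::export]]
NumericMatrix cpp_median2d(NumericMatrix m, int hw, int min_n) {
  const int nx = m.nrow(), ny = m.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> buf;
  buf.reserve((2 * hw + 1) * (2 * hw + 1));
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!R_finite(m(i, j))) { out(i, j) = NA_REAL; continue; }
      buf.clear();
      for (int q = std::max(0, j - hw); q <= std::min(ny - 1, j + hw); ++q)
        for (int p = std::max(0, i - hw); p <= std::min(nx - 1, i + hw); ++p)
          if (R_finite(m(p, q))) buf.push_back(m(p, q));
      if ((int)buf.size() < min_n) { out(i, j) = NA_REAL; continue; }
      const size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  return out;
}
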