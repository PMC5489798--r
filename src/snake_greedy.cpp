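// Greedy discrete energy minimization for active contours.
//
// Each sweep visits every contour point in order and moves it to the
// candidate position in its (2R+1)^2 neighborhood (scaled by `step`) that
// lowers the total snake energy the most; a move is accepted only if the
// exact total-energy change, restricted to the terms the move touches
// (continuity of i and i+1, curvature of i-1, i, i+1, external at i), is
// negative. The total energy is therefore non-increasing after every
// sweep. For the mean-spacing continuity form the reference spacing dbar
// is frozen at call entry so the minimized functional is fixed.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Field {
  const NumericMatrix &f;
  int nr, nc;
  explicit Field(const NumericMatrix &m) : f(m), nr(m.nrow()), nc(m.ncol()) {}
  // bilinear interpolation at 1-based (r, c), clamped to the grid
  double at(double r, double c) const {
    if (r < 1) r = 1; if (r > nr) r = nr;
    if (c < 1) c = 1; if (c > nc) c = nc;
    int i0 = (int)std::floor(r); if (i0 > nr - 1) i0 = nr - 1; if (i0 < 1) i0 = 1;
    int j0 = (int)std::floor(c); if (j0 > nc - 1) j0 = nc - 1; if (j0 < 1) j0 = 1;
    double fr = r - i0, fc = c - j0;
    double v00 = f(i0 - 1, j0 - 1), v10 = f(i0, j0 - 1);
    double v01 = f(i0 - 1, j0), v11 = f(i0, j0);
    return v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
           v01 * (1 - fr) * fc + v11 * fr * fc;
  }
};

inline double sq(double x) { return x * x; }

class SnakeEnergy {
public:
  std::vector<double> r, c;
  int n;
  bool closed, meanSpacing;
  double alpha, beta, dbar;
  const Field &field;

  SnakeEnergy(const NumericMatrix &pts, const Field &fld, double a, double b,
              bool closed_, bool meanSp)
      : n(pts.nrow()), closed(closed_), meanSpacing(meanSp), alpha(a),
        beta(b), field(fld) {
    r.resize(n); c.resize(n);
    for (int i = 0; i < n; ++i) { r[i] = pts(i, 0); c[i] = pts(i, 1); }
    dbar = meanSpacing ? meanSpacingNow() : 0.0;
  }

  double meanSpacingNow() const {
    double s = 0; int m = 0;
    for (int i = 1; i < n; ++i) {
      s += std::hypot(r[i] - r[i - 1], c[i] - c[i - 1]); ++m;
    }
    if (closed) { s += std::hypot(r[0] - r[n - 1], c[0] - c[n - 1]); ++m; }
    return m ? s / m : 0.0;
  }

  int prev(int i) const { return i > 0 ? i - 1 : (closed ? n - 1 : -1); }
  int next(int i) const { return i < n - 1 ? i + 1 : (closed ? 0 : -1); }

  // continuity term attached to point i (edge from prev(i) to i)
  double cont(int i, double ri, double ci) const {
    int p = prev(i);
    if (p < 0) return 0.0;
    double d = std::hypot(ri - r[p], ci - c[p]);
    return alpha * (meanSpacing ? sq(dbar - d) : sq(d));
  }
  double contAt(int i) const { return cont(i, r[i], c[i]); }

  // curvature term at point i with point j displaced to (rj, cj)
  double curvDisp(int i, int j, double rj, double cj) const {
    int p = prev(i), q = next(i);
    if (p < 0 || q < 0) return 0.0;
    double rp = (p == j) ? rj : r[p], cp = (p == j) ? cj : c[p];
    double ri = (i == j) ? rj : r[i], ci = (i == j) ? cj : c[i];
    double rq = (q == j) ? rj : r[q], cq = (q == j) ? cj : c[q];
    return beta * (sq(rp - 2 * ri + rq) + sq(cp - 2 * ci + cq));
  }

  // terms of the total energy affected by moving point i to (ri, ci)
  double local(int i, double ri, double ci) const {
    double e = cont(i, ri, ci) + field.at(ri, ci);
    int q = next(i);
    if (q >= 0) {   // edge (i, next) is next's continuity term
      double d = std::hypot(r[q] - ri, c[q] - ci);
      e += alpha * (meanSpacing ? sq(dbar - d) : sq(d));
    }
    int p = prev(i);
    if (p >= 0) e += curvDisp(p, i, ri, ci);
    e += curvDisp(i, i, ri, ci);
    if (q >= 0) e += curvDisp(q, i, ri, ci);
    return e;
  }

  double total() const {
    double e = 0;
    for (int i = 0; i < n; ++i) {
      e += contAt(i) + curvDisp(i, i, r[i], c[i]) + field.at(r[i], c[i]);
    }
    return e;
  }
};

} // namespace

// [[Rcpp::export]]
List snake_greedy_cpp(NumericMatrix pts, NumericMatrix field, double alpha,
                      double beta, bool mean_spacing, bool closed,
                      NumericVector steps, int max_iter, int search_radius) {
  Field fld(field);
  SnakeEnergy sn(pts, fld, alpha, beta, closed, mean_spacing);
  std::vector<double> trace;
  trace.push_back(sn.total());
  int sweeps = 0;

  for (int si = 0; si < steps.size(); ++si) {
    double step = steps[si];
    for (int it = 0; it < max_iter; ++it) {
      int moved = 0;
      for (int i = 0; i < sn.n; ++i) {
        double bestR = sn.r[i], bestC = sn.c[i];
        double cur = sn.local(i, bestR, bestC);
        double best = cur;
        for (int dr = -search_radius; dr <= search_radius; ++dr) {
          for (int dc = -search_radius; dc <= search_radius; ++dc) {
            if (dr == 0 && dc == 0) continue;
            double rr = sn.r[i] + dr * step, cc = sn.c[i] + dc * step;
            if (rr < 1) rr = 1; if (rr > fld.nr) rr = fld.nr;
            if (cc < 1) cc = 1; if (cc > fld.nc) cc = fld.nc;
            double e = sn.local(i, rr, cc);
            if (e < best - 1e-12) { best = e; bestR = rr; bestC = cc; }
          }
        }
        if (best < cur - 1e-12) {
          sn.r[i] = bestR; sn.c[i] = bestC; ++moved;
        }
      }
      ++sweeps;
      trace.push_back(sn.total());
      if (moved == 0) break;
    }
  }

  NumericMatrix out(sn.n, 2);
  for (int i = 0; i < sn.n; ++i) { out(i, 0) = sn.r[i]; out(i, 1) = sn.c[i]; }
  return List::create(_["points"] = out,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["sweeps"] = sweeps);
}
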