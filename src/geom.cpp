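#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 8-connected component labelling of a binary mask (iterative flood fill).
// Returns an integer matrix: 0 = background, 1..k = component labels.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int cur = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++cur;
      lab(i, j) = cur;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = cur;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Scanline even-odd fill of a closed polygon onto an ny x nx pixel grid.
// Pixel (row r, col c) has centre (x = c, y = r) in 1-based grid units;
// the caller handles any y-flip.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_polygon(NumericVector px, NumericVector py,
                               int nx, int ny) {
  LogicalMatrix out(ny, nx);
  int n = px.size();
  std::vector<double> xs;
  for (int r = 0; r < ny; ++r) {
    double yc = r + 1.0;
    xs.clear();
    for (int k = 0; k < n; ++k) {
      int k2 = (k + 1) % n;
      double y1 = py[k], y2 = py[k2];
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        double t = (yc - y1) / (y2 - y1);
        xs.push_back(px[k] + t * (px[k2] - px[k]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t m = 0; m + 1 < xs.size(); m += 2) {
      int c1 = (int)std::ceil(xs[m]);
      int c2 = (int)std::floor(xs[m + 1]);
      if (c1 < 1) c1 = 1;
      if (c2 > nx) c2 = nx;
      for (int c = c1; c <= c2; ++c) out(r, c - 1) = true;
    }
  }
  return out;
}

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// Sutherland-Hodgman clip of a polygon by the half-plane left of a->b.
static void clip_half(std::vector<double>& sx, std::vector<double>& sy,
                      double ax, double ay, double bx, double by) {
  std::vector<double> rx, ry;
  int n = (int)sx.size();
  rx.reserve(n + 4); ry.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double ci = cross3(ax, ay, bx, by, sx[i], sy[i]);
    double cj = cross3(ax, ay, bx, by, sx[j], sy[j]);
    bool ini = ci >= 0, inj = cj >= 0;
    if (ini) { rx.push_back(sx[i]); ry.push_back(sy[i]); }
    if (ini != inj) {
      double t = ci / (ci - cj);
      rx.push_back(sx[i] + t * (sx[j] - sx[i]));
      ry.push_back(sy[i] + t * (sy[j] - sy[i]));
    }
  }
  sx.swap(rx); sy.swap(ry);
}

static double signed_area_vec(const std::vector<double>& x,
                              const std::vector<double>& y) {
  double a = 0; int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

// Exact area of intersection of two simple polygons.
// P is decomposed into a signed triangle fan about its vertex centroid
// (winding of the fan reproduces the indicator of P); each convex fan
// triangle clips Q by Sutherland-Hodgman, and signed pieces accumulate.
// [[Rcpp::export]]
double cpp_intersection_area(NumericMatrix P, NumericMatrix Q) {
  int np = P.nrow(), nq = Q.nrow();
  if (np < 3 || nq < 3) return 0.0;
  double ox = 0, oy = 0;
  for (int i = 0; i < np; ++i) { ox += P(i, 0); oy += P(i, 1); }
  ox /= np; oy /= np;
  // bounding box of Q for cheap pruning
  double qx0 = Q(0, 0), qx1 = Q(0, 0), qy0 = Q(0, 1), qy1 = Q(0, 1);
  for (int k = 1; k < nq; ++k) {
    qx0 = std::min(qx0, Q(k, 0)); qx1 = std::max(qx1, Q(k, 0));
    qy0 = std::min(qy0, Q(k, 1)); qy1 = std::max(qy1, Q(k, 1));
  }
  std::vector<double> sx, sy;
  double total = 0;
  for (int i = 0; i < np; ++i) {
    int j = (i + 1) % np;
    double ax = P(i, 0), ay = P(i, 1), bx = P(j, 0), by = P(j, 1);
    double s = cross3(ox, oy, ax, ay, bx, by);
    if (std::fabs(s) < 1e-300) continue;
    double sgn = s > 0 ? 1.0 : -1.0;
    double t2x, t2y, t3x, t3y;
    if (sgn > 0) { t2x = ax; t2y = ay; t3x = bx; t3y = by; }
    else         { t2x = bx; t2y = by; t3x = ax; t3y = ay; }
    double tx0 = std::min(ox, std::min(t2x, t3x));
    double tx1 = std::max(ox, std::max(t2x, t3x));
    double ty0 = std::min(oy, std::min(t2y, t3y));
    double ty1 = std::max(oy, std::max(t2y, t3y));
    if (tx1 < qx0 || tx0 > qx1 || ty1 < qy0 || ty0 > qy1) continue;
    sx.assign(nq, 0); sy.assign(nq, 0);
    for (int k = 0; k < nq; ++k) { sx[k] = Q(k, 0); sy[k] = Q(k, 1); }
    clip_half(sx, sy, ox, oy, t2x, t2y);
    if (sx.size() < 3) continue;
    clip_half(sx, sy, t2x, t2y, t3x, t3y);
    if (sx.size() < 3) continue;
    clip_half(sx, sy, t3x, t3y, ox, oy);
    if (sx.size() < 3) continue;
    total += sgn * signed_area_vec(sx, sy);
  }
  return total;
}
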