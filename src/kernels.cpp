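#include <Rcpp.h>
using namespace Rcpp;

// Minimum distance from every pixel center to a polyline, computed only
// inside a band of half-width `band` around each segment (pixels outside
// every band keep the sentinel value band + 1).  Pixel centers sit at
// integer coordinates, 0-based: x = column - 1, y = row - 1.
// [[Rcpp::export]]
NumericMatrix cpp_polyline_distance(NumericVector px, NumericVector py,
                                    int nrow, int ncol, double band) {
  const int n = px.size();
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), band + 1.0);
  if (n == 0) return out;
  const double pad = band + 1.0;
  for (int k = 0; k < std::max(1, n - 1); ++k) {
    const double ax = px[k], ay = py[k];
    const double bx = (n > 1) ? px[k + 1] : ax;
    const double by = (n > 1) ? py[k + 1] : ay;
    const double dx = bx - ax, dy = by - ay;
    const double len2 = dx * dx + dy * dy;
    int x0 = (int)std::floor(std::min(ax, bx) - pad);
    int x1 = (int)std::ceil(std::max(ax, bx) + pad);
    int y0 = (int)std::floor(std::min(ay, by) - pad);
    int y1 = (int)std::ceil(std::max(ay, by) + pad);
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (x1 > ncol - 1) x1 = ncol - 1;
    if (y1 > nrow - 1) y1 = nrow - 1;
    for (int y = y0; y <= y1; ++y) {
      for (int x = x0; x <= x1; ++x) {
        double t = 0.0;
        if (len2 > 0.0) {
          t = ((x - ax) * dx + (y - ay) * dy) / len2;
          if (t < 0.0) t = 0.0;
          if (t > 1.0) t = 1.0;
        }
        const double qx = ax + t * dx - x;
        const double qy = ay + t * dy - y;
        const double d = std::sqrt(qx * qx + qy * qy);
        if (d < out(y, x)) out(y, x) = d;
      }
    }
  }
  return out;
}

static inline int nb(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// Zhang-Suen thinning of a 0/1 mask down to a 1-pixel-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  const int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (m(r, c) == 0) continue;
          // neighbours P2..P9 clockwise from north
          int p[8];
          p[0] = nb(m, r - 1, c);     // P2
          p[1] = nb(m, r - 1, c + 1); // P3
          p[2] = nb(m, r, c + 1);     // P4
          p[3] = nb(m, r + 1, c + 1); // P5
          p[4] = nb(m, r + 1, c);     // P6
          p[5] = nb(m, r + 1, c - 1); // P7
          p[6] = nb(m, r, c - 1);     // P8
          p[7] = nb(m, r - 1, c - 1); // P9
          int b = 0, a = 0;
          for (int i = 0; i < 8; ++i) {
            b += p[i];
            if (p[i] == 0 && p[(i + 1) % 8] == 1) ++a;
          }
          if (b < 2 || b > 6 || a != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          m(kill[i].first, kill[i].second) = 0;
      }
    }
  }
  return m;
}
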