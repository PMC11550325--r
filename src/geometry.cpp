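#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Scanline even-odd polygon fill. Coordinate convention: origin top-left,
// x rightward (columns), y downward (rows); pixel (r, c) owns the half-open
// cell [c, c+1) x [r, r+1) and is tested at its centre (c+0.5, r+0.5).
// A centre lying exactly on a span boundary is resolved half-open
// [x_enter, x_exit), which keeps integer-cornered rectangles exact.
// [[Rcpp::export]]
LogicalMatrix rasterize_ring_cpp(NumericVector x, NumericVector y,
                                 int width, int height) {
  int n = x.size();
  LogicalMatrix out(height, width);
  std::vector<double> xs;
  xs.reserve(n);
  for (int r = 0; r < height; ++r) {
    double yc = r + 0.5;
    xs.clear();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1 == n) ? 0 : i + 1;
      double y1 = y[i], y2 = y[j];
      // half-open crossing rule: counts each vertex-level crossing once
      if ((y1 <= yc) != (y2 <= yc)) {
        double t = (yc - y1) / (y2 - y1);
        xs.push_back(x[i] + t * (x[j] - x[i]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      // pixels with x_enter <= c+0.5 < x_exit
      int c0 = (int)std::ceil(xs[k] - 0.5);
      int c1 = (int)std::ceil(xs[k + 1] - 0.5) - 1;
      if (c0 < 0) c0 = 0;
      if (c1 > width - 1) c1 = width - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = true;
    }
  }
  return out;
}

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static inline bool on_segment(double px, double py, double qx, double qy,
                              double rx, double ry) {
  return std::min(px, qx) <= rx && rx <= std::max(px, qx) &&
         std::min(py, qy) <= ry && ry <= std::max(py, qy);
}

static bool segments_meet(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  double d1 = cross3(cx, cy, dx, dy, ax, ay);
  double d2 = cross3(cx, cy, dx, dy, bx, by);
  double d3 = cross3(ax, ay, bx, by, cx, cy);
  double d4 = cross3(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  if (d1 == 0 && on_segment(cx, cy, dx, dy, ax, ay)) return true;
  if (d2 == 0 && on_segment(cx, cy, dx, dy, bx, by)) return true;
  if (d3 == 0 && on_segment(ax, ay, bx, by, cx, cy)) return true;
  if (d4 == 0 && on_segment(ax, ay, bx, by, dx, dy)) return true;
  return false;
}

// TRUE iff the closed ring (implicit last->first edge) has no two
// non-adjacent edges that intersect or touch. Adjacent edges share a
// vertex by construction and are skipped.
// [[Rcpp::export]]
bool ring_is_simple_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1 == n) ? 0 : i + 1;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1 == n) ? 0 : j + 1;
      if (j == i2 || j2 == i) continue;  // adjacent edges
      if (segments_meet(x[i], y[i], x[i2], y[i2], x[j], y[j], x[j2], y[j2]))
        return false;
    }
  }
  return true;
}

// CRC-32 (ISO 3309, as used by PNG). Returned as double: R has no uint32.
// [[Rcpp::export]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// One-pass overlap counts: tp, fp, fn.
// [[Rcpp::export]]
IntegerVector overlap_counts_cpp(LogicalMatrix gt, LogicalMatrix p) {
  R_xlen_t n = gt.size();
  int tp = 0, fp = 0, fn = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (gt[i]) { if (p[i]) ++tp; else ++fn; }
    else if (p[i]) ++fp;
  }
  return IntegerVector::create(tp, fp, fn);
}

// Mean of true-pixel centres, (row, col), 0-based continuous coordinates.
// [[Rcpp::export]]
NumericVector mask_centroid_cpp(LogicalMatrix m) {
  double sr = 0, sc = 0;
  R_xlen_t cnt = 0;
  for (int c = 0; c < m.ncol(); ++c)
    for (int r = 0; r < m.nrow(); ++r)
      if (m(r, c)) { sr += r + 0.5; sc += c + 0.5; ++cnt; }
  if (cnt == 0) return NumericVector::create(NA_REAL, NA_REAL);
  return NumericVector::create(sr / cnt, sc / cnt);
}
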