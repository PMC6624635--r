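#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat grayscale erosion with an explicit offset set (rows, cols).
// Out-of-bounds offsets are ignored (morphology restricted to the image
// domain), which keeps the derived opening idempotent and anti-extensive.
// [[Rcpp::export]]
NumericMatrix cpp_flat_erode(const NumericMatrix& img, const IntegerMatrix& off) {
  const int H = img.nrow(), W = img.ncol(), n = off.nrow();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m = R_PosInf;
      for (int k = 0; k < n; ++k) {
        int rr = r + off(k, 0), cc = c + off(k, 1);
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        double v = img(rr, cc);
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_flat_dilate(const NumericMatrix& img, const IntegerMatrix& off) {
  const int H = img.nrow(), W = img.ncol(), n = off.nrow();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m = R_NegInf;
      for (int k = 0; k < n; ++k) {
        int rr = r + off(k, 0), cc = c + off(k, 1);
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        double v = img(rr, cc);
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Gradient-maximization threshold selection: over nlevels uniformly spaced
// candidate levels on [lo, hi] (bin midpoints, so candidates are strictly
// interior), pick the threshold whose class boundary (pixels 8-adjacent to
// the opposite class) has maximal mean gradient magnitude. Ties are broken
// toward the lower threshold.
// [[Rcpp::export]]
List cpp_gradient_threshold(const NumericMatrix& map, const NumericMatrix& grad,
                            int nlevels) {
  const int H = map.nrow(), W = map.ncol();
  double lo = R_PosInf, hi = R_NegInf;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double v = map(r, c);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
  if (!(hi > lo)) stop("constant map");
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  NumericVector crit(nlevels, NA_REAL), thr(nlevels);
  double best = R_NegInf;
  int besti = -1;
  for (int i = 0; i < nlevels; ++i) {
    double t = lo + (hi - lo) * (i + 0.5) / nlevels;
    thr[i] = t;
    double s = 0.0;
    long nb = 0;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        bool above = map(r, c) > t;
        bool boundary = false;
        for (int k = 0; k < 8 && !boundary; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if ((map(rr, cc) > t) != above) boundary = true;
        }
        if (boundary) { s += grad(r, c); ++nb; }
      }
    }
    if (nb == 0) continue;
    double m = s / nb;
    crit[i] = m;
    if (m > best) { best = m; besti = i; }
  }
  if (besti < 0) stop("constant map");
  return List::create(_["threshold"] = thr[besti], _["index"] = besti + 1,
                      _["criterion"] = crit, _["candidates"] = thr);
}

// Adaptive grayscale erosion with a per-pixel elliptical flat SE
// (orientation theta of the major axis, semi-axes a >= b, center-inclusive).
// [[Rcpp::export]]
NumericMatrix cpp_adaptive_erode(const NumericMatrix& img, const NumericMatrix& theta,
                                 const NumericMatrix& a, const NumericMatrix& b) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double aa = a(r, c), bb = b(r, c), th = theta(r, c);
      double ct = std::cos(th), st = std::sin(th);
      int R = (int)std::floor(aa);
      double m = img(r, c);
      for (int dy = -R; dy <= R; ++dy) {
        int rr = r + dy;
        if (rr < 0 || rr >= H) continue;
        for (int dx = -R; dx <= R; ++dx) {
          int cc = c + dx;
          if (cc < 0 || cc >= W) continue;
          // x = column offset, y = row offset
          double u = dx * ct + dy * st;   // along major axis
          double w = -dx * st + dy * ct;  // along minor axis
          if ((u * u) / (aa * aa) + (w * w) / (bb * bb) <= 1.0) {
            double v = img(rr, cc);
            if (v < m) m = v;
          }
        }
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Connected-component labeling of a 0/1 mask, 4- or 8-connectivity.
// Components numbered 1..K in raster (column-major) discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int conn) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (conn == 8) ? dr8 : dr4;
  const int* dc = (conn == 8) ? dc8 : dc4;
  const int nn = (conn == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % H, cc2 = idx / H;
        for (int k = 0; k < nn; ++k) {
          int rr = cr + dr[k], cc = cc2 + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}

struct WsNode {
  double v;
  long long ord;
  int idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode& x, const WsNode& y) const {
    if (x.v != y.v) return x.v > y.v;      // min-heap on flooding value
    return x.ord > y.ord;                  // then insertion order
  }
};

// Marker-controlled watershed: flood the surface from the seed labels,
// restricted to mask pixels. Deterministic: priority by (value, insertion).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& surface, const IntegerMatrix& seeds,
                            const LogicalMatrix& mask, int conn) {
  const int H = surface.nrow(), W = surface.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (conn == 8) ? dr8 : dr4;
  const int* dc = (conn == 8) ? dc8 : dc4;
  const int nn = (conn == 8) ? 8 : 4;
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long ord = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (seeds(r, c) > 0) {
        lab(r, c) = seeds(r, c);
        pq.push({surface(r, c), ord++, r + c * H, seeds(r, c)});
      }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int r = nd.idx % H, c = nd.idx / H;
    for (int k = 0; k < nn; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
      lab(rr, cc) = nd.lab;
      pq.push({surface(rr, cc), ord++, rr + cc * H, nd.lab});
    }
  }
  return lab;
}
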