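// Low-level raster primitives used by the segmentation and zoning code.
// R matrices are column-major; (i, j) = (row, col), 0-based internally.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in pixels) from each pixel to the nearest
// pixel where mask == 0 (background). Background pixels get 0.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // columns first (large finite sentinel: INF would give NaN in dt1d)
  const double BIG = 1e20;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? BIG : 0.0;
    dt1d(f, d, nr, v, z);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // then rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, nc, v, z);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// Connected-component labelling of mask != 0. Labels assigned in
// column-major scan order (deterministic), contiguous from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity = 4) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qi, qj;
  int next = 0;
  int di4[] = {-1, 1, 0, 0}, dj4[] = {0, 0, -1, 1};
  int di8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dj8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int* di = (connectivity == 8) ? di8 : di4;
  int* dj = (connectivity == 8) ? dj8 : dj4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = next;
      size_t head = 0;
      while (head < qi.size()) {
        int ci = qi[head], cj = qj[head];
        ++head;
        for (int k = 0; k < nn; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  }
  return lab;
}

// van Herk / Gil-Werman sliding extreme over window [q-w, q+w] on a
// contiguous array; values outside [0, n) are ignored (sentinel-padded).
static void vh_extreme(const double* x, double* out, int n, int w,
                       bool take_min, std::vector<double>& pad,
                       std::vector<double>& pre, std::vector<double>& suf) {
  if (w == 0) { std::copy(x, x + n, out); return; }
  int L = 2 * w + 1;
  int np = ((n + L - 1) / L) * L + 2 * w;  // padded, multiple-of-L core
  double sentinel = take_min ? INF : -INF;
  if ((int)pad.size() < np) { pad.resize(np); pre.resize(np); suf.resize(np); }
  for (int q = 0; q < np; ++q)
    pad[q] = (q >= w && q - w < n) ? x[q - w] : sentinel;
  // prefix extremes within blocks of L, suffix extremes within blocks
  for (int b = 0; b < np; b += L) {
    int hi = std::min(b + L, np);
    pre[b] = pad[b];
    for (int q = b + 1; q < hi; ++q)
      pre[q] = take_min ? std::min(pre[q - 1], pad[q])
                        : std::max(pre[q - 1], pad[q]);
    suf[hi - 1] = pad[hi - 1];
    for (int q = hi - 2; q >= b; --q)
      suf[q] = take_min ? std::min(suf[q + 1], pad[q])
                        : std::max(suf[q + 1], pad[q]);
  }
  // window around padded position q+w spans [q, q+2w]
  for (int q = 0; q < n; ++q) {
    double a = suf[q], b = pre[q + 2 * w];
    out[q] = take_min ? std::min(a, b) : std::max(a, b);
  }
}

static NumericMatrix disk_extreme(const NumericMatrix& img, int radius,
                                  bool take_min) {
  int nr = img.nrow(), nc = img.ncol();
  double sentinel = take_min ? INF : -INF;
  // distinct horizontal half-widths across row offsets
  std::vector<int> wof(2 * radius + 1);
  std::vector<int> distinct;
  for (int dy = -radius; dy <= radius; ++dy) {
    int w = (int)std::floor(std::sqrt((double)radius * radius -
                                      (double)dy * dy));
    wof[dy + radius] = w;
    if (std::find(distinct.begin(), distinct.end(), w) == distinct.end())
      distinct.push_back(w);
  }
  // work in transposed (row-contiguous) layout throughout
  std::vector<double> timg((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) timg[(size_t)i * nc + j] = img(i, j);
  std::vector<std::vector<double> > H(distinct.size());
  std::vector<double> pad, pre, suf;
  for (size_t t = 0; t < distinct.size(); ++t) {
    H[t].resize((size_t)nr * nc);
    for (int i = 0; i < nr; ++i)
      vh_extreme(&timg[(size_t)i * nc], &H[t][(size_t)i * nc], nc,
                 distinct[t], take_min, pad, pre, suf);
  }
  std::vector<int> which_w(2 * radius + 1);
  for (int dy = -radius; dy <= radius; ++dy)
    which_w[dy + radius] =
      (int)(std::find(distinct.begin(), distinct.end(), wof[dy + radius]) -
            distinct.begin());
  std::vector<double> outt((size_t)nr * nc, sentinel);
  for (int dy = -radius; dy <= radius; ++dy) {
    const std::vector<double>& h = H[which_w[dy + radius]];
    int i0 = std::max(0, -dy), i1 = std::min(nr, nr - dy);
    for (int i = i0; i < i1; ++i) {
      const double* src = &h[(size_t)(i + dy) * nc];
      double* dst = &outt[(size_t)i * nc];
      if (take_min) {
        for (int j = 0; j < nc; ++j) if (src[j] < dst[j]) dst[j] = src[j];
      } else {
        for (int j = 0; j < nc; ++j) if (src[j] > dst[j]) dst[j] = src[j];
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = outt[(size_t)i * nc + j];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_erode_disk(NumericMatrix img, int radius) {
  return disk_extreme(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_disk(NumericMatrix img, int radius) {
  return disk_extreme(img, radius, false);
}

// Median filter with a disk structuring element (brute force; used only at
// small radii). Border handled by taking the median over the intersection.
// [[Rcpp::export]]
NumericMatrix cpp_median_disk(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> oi, oj;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= radius * radius) { oi.push_back(dy); oj.push_back(dx); }
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(oi.size());
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (size_t k = 0; k < oi.size(); ++k) {
        int ni = i + oi[k], nj = j + oj[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        buf.push_back(img(ni, nj));
      }
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}

struct WsNode {
  double priority;
  long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.priority != b.priority) return a.priority > b.priority;
    return a.order > b.order;  // FIFO among equal priorities -> deterministic
  }
};

// Marker-based watershed by priority flooding: pixels inside mask are
// assigned the label of the marker basin that reaches them first along
// increasing `priority` (use -elevation to flood from peaks).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority_, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = priority_.nrow(), nc = priority_.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      lab(i, j) = markers(i, j);
      if (markers(i, j) > 0 && mask(i, j))
        pq.push({priority_(i, j), order++, i + j * nr, markers(i, j)});
    }
  int di[] = {-1, 1, 0, 0}, dj[] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int ci = nd.idx % nr, cj = nd.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ni = ci + di[k], nj = cj + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = nd.label;
      pq.push({priority_(ni, nj), order++, ni + nj * nr, nd.label});
    }
  }
  return lab;
}

// Assign each non-nucleus pixel within `band_px` of a labelled nucleus to its
// nearest nucleus (exact Euclidean, tie -> lower label). Returns the ring
// label image (0 elsewhere and on nuclei).
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_label_band(IntegerMatrix labels, double band_px) {
  int nr = labels.nrow(), nc = labels.ncol();
  int r = (int)std::ceil(band_px);
  struct Off { int di, dj; double d2; };
  std::vector<Off> offs;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj) {
      double d2 = (double)di * di + (double)dj * dj;
      if (d2 > 0 && d2 <= band_px * band_px) offs.push_back({di, dj, d2});
    }
  std::stable_sort(offs.begin(), offs.end(),
                   [](const Off& a, const Off& b) { return a.d2 < b.d2; });
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (labels(i, j) != 0) continue;
      double best_d2 = INF;
      int best_lab = 0;
      for (size_t k = 0; k < offs.size(); ++k) {
        if (offs[k].d2 > best_d2) break;  // offsets sorted: done
        int ni = i + offs[k].di, nj = j + offs[k].dj;
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int l = labels(ni, nj);
        if (l > 0) {
          if (offs[k].d2 < best_d2 || (offs[k].d2 == best_d2 && l < best_lab)) {
            best_d2 = offs[k].d2;
            best_lab = l;
          }
        }
      }
      out(i, j) = best_lab;
    }
  }
  return out;
}
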