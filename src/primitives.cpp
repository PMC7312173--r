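#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Raster primitives backing segmentation and feature extraction.
// Convention throughout: images are R matrices indexed [row, col], 0-based here.

// ---- separable convolution with reflect padding ------------------------------

static inline int reflect_idx(int i, int n) {
  // reflect-101 style: ...2 1 0 1 2... keeps edges unbiased
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol(), k = kernel.size(), h = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical pass)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int j = 0; j < k; ++j) s += kernel[j] * img(reflect_idx(r + j - h, nr), c);
      tmp(r, c) = s;
    }
  // along cols (horizontal pass)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int j = 0; j < k; ++j) s += kernel[j] * tmp(r, reflect_idx(c + j - h, nc));
      out(r, c) = s;
    }
  return out;
}

// ---- connected components (4-connectivity) -----------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix bin) {
  int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!bin(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 4; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (bin(qr, qc) && !lab(qr, qc)) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  return lab;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) --------

static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// distance of each true (foreground) pixel to the nearest false (background) pixel
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) g(r, c) = fg(r, c) ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {           // columns pass
    for (int r = 0; r < nr; ++r) f[r] = g(r, c);
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {           // rows pass
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) g(r, c) = std::sqrt(d[c]);
  }
  return g;
}

// ---- seeded watershed (ascending priority flood, 4-connected) ----------------

struct WsNode {
  double v; long ord; int pos;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.v != b.v) return a.v > b.v;     // min-heap on value
    return a.ord > b.ord;                  // FIFO ties -> deterministic
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix img, IntegerMatrix seeds, LogicalMatrix mask) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long ord = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({img(r, c), ord++, r + c * nr});
      }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int pr = nd.pos % nr, pc = nd.pos / nr;
    int l = lab(pr, pc);
    for (int k = 0; k < 4; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (!mask(qr, qc) || lab(qr, qc)) continue;
      lab(qr, qc) = l;
      pq.push({img(qr, qc), ord++, qr + qc * nr});
    }
  }
  return lab;
}

// ---- grayscale morphology over an arbitrary flat structuring element ---------
// offsets: n x 2 integer matrix of (dr, dc). Pixels outside the image are
// treated as +Inf for erosion / -Inf for dilation (border-neutral).

// [[Rcpp::export]]
NumericMatrix cpp_erode_gray(NumericMatrix img, IntegerMatrix offsets) {
  int nr = img.nrow(), nc = img.ncol(), n = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = std::numeric_limits<double>::infinity();
      for (int k = 0; k < n; ++k) {
        int qr = r + offsets(k, 0), qc = c + offsets(k, 1);
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (img(qr, qc) < m) m = img(qr, qc);
      }
      out(r, c) = m;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_gray(NumericMatrix img, IntegerMatrix offsets) {
  int nr = img.nrow(), nc = img.ncol(), n = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < n; ++k) {
        int qr = r + offsets(k, 0), qc = c + offsets(k, 1);
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (img(qr, qc) > m) m = img(qr, qc);
      }
      out(r, c) = m;
    }
  return out;
}

// ---- morphological reconstruction by dilation (marker under mask) ------------
// Vincent's sequential raster/anti-raster sweeps followed by a FIFO queue.

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) J(r, c) = std::min(marker(r, c), mask(r, c));
  // forward sweep: neighbors already visited are up and left
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      if (r > 0 && J(r - 1, c) > m) m = J(r - 1, c);
      if (c > 0 && J(r, c - 1) > m) m = J(r, c - 1);
      J(r, c) = std::min(m, mask(r, c));
    }
  std::queue<int> fifo;
  // backward sweep
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      if (r < nr - 1 && J(r + 1, c) > m) m = J(r + 1, c);
      if (c < nc - 1 && J(r, c + 1) > m) m = J(r, c + 1);
      J(r, c) = std::min(m, mask(r, c));
      // queue pixels whose down/right neighbor could still grow
      bool push = false;
      if (r < nr - 1 && J(r + 1, c) < J(r, c) && J(r + 1, c) < mask(r + 1, c)) push = true;
      if (c < nc - 1 && J(r, c + 1) < J(r, c) && J(r, c + 1) < mask(r, c + 1)) push = true;
      if (push) fifo.push(r + c * nr);
    }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int pr = p % nr, pc = p / nr;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (J(qr, qc) < J(pr, pc) && J(qr, qc) < mask(qr, qc)) {
        J(qr, qc) = std::min(J(pr, pc), mask(qr, qc));
        fifo.push(qr + qc * nr);
      }
    }
  }
  return J;
}

// ---- regional maxima (8-connected plateaus with no greater neighbor) ---------

// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(NumericMatrix img, LogicalMatrix mask) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);   // 0 = not a maximum; k>0 labels each maximal plateau
  IntegerMatrix seen(nr, nc);
  std::vector<int> comp;
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1}, dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || seen(r, c)) continue;
      double v = img(r, c);
      // BFS over the equal-valued plateau restricted to mask
      comp.clear();
      std::vector<int> stack;
      stack.push_back(r + c * nr);
      seen(r, c) = 1;
      bool is_max = true;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        comp.push_back(p);
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (!mask(qr, qc)) continue;
          double w = img(qr, qc);
          if (w > v) is_max = false;
          else if (w == v && !seen(qr, qc)) {
            seen(qr, qc) = 1;
            stack.push_back(qr + qc * nr);
          }
        }
      }
      if (is_max) {
        ++next;
        for (size_t i = 0; i < comp.size(); ++i)
          lab(comp[i] % nr, comp[i] / nr) = next;
      }
    }
  return lab;
}

// ---- per-label accumulators (bounding boxes, sums, counts) -------------------

// [[Rcpp::export]]
List cpp_label_stats(IntegerMatrix lab, NumericMatrix img, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerVector count(nlab), rmin(nlab, nr), rmax(nlab, -1), cmin(nlab, nc), cmax(nlab, -1);
  NumericVector sum(nlab), rsum(nlab), csum(nlab);
  bool has_img = img.nrow() == nr && img.ncol() == nc;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l <= 0 || l > nlab) continue;
      int i = l - 1;
      count[i]++;
      rsum[i] += r + 1;  // 1-based for R
      csum[i] += c + 1;
      if (r < rmin[i]) rmin[i] = r;
      if (r > rmax[i]) rmax[i] = r;
      if (c < cmin[i]) cmin[i] = c;
      if (c > cmax[i]) cmax[i] = c;
      if (has_img) sum[i] += img(r, c);
    }
  return List::create(_["count"] = count, _["sum"] = sum,
                      _["rmean"] = rsum, _["cmean"] = csum,
                      _["rmin"] = rmin + 1, _["rmax"] = rmax + 1,
                      _["cmin"] = cmin + 1, _["cmax"] = cmax + 1);
}

// ---- gray-level co-occurrence accumulation -----------------------------------
// q: quantized levels (1..levels) with 0 outside the region; one offset (dr,dc).
// Returns the symmetrized, unnormalized GLCM.

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerMatrix q, int levels, int dr, int dc) {
  int nr = q.nrow(), nc = q.ncol();
  NumericMatrix P(levels, levels);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int a = q(r, c);
      if (a <= 0) continue;
      int qr = r + dr, qc = c + dc;
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int b = q(qr, qc);
      if (b <= 0) continue;
      P(a - 1, b - 1) += 1.0;
      P(b - 1, a - 1) += 1.0;
    }
  return P;
}
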