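#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Region statistics tracked incrementally: n, sum, sum of squares, min, max.
struct RegStat {
  double n = 0, sum = 0, sumsq = 0;
  double mn = R_PosInf, mx = R_NegInf;
  void add(double v) {
    n += 1; sum += v; sumsq += v * v;
    if (v < mn) mn = v;
    if (v > mx) mx = v;
  }
  double mean() const { return sum / n; }
  double sd() const {
    if (n < 2) return 0.0;
    double v = (sumsq - sum * sum / n) / (n - 1);
    return v > 0 ? std::sqrt(v) : 0.0;
  }
  RegStat merged(const RegStat &o) const {
    RegStat r;
    r.n = n + o.n; r.sum = sum + o.sum; r.sumsq = sumsq + o.sumsq;
    r.mn = std::min(mn, o.mn); r.mx = std::max(mx, o.mx);
    return r;
  }
};

// Region-level homogeneity predicate: intensity range within the cap.
// A range cap, unlike a dispersion cap, is insensitive to the size
// imbalance of a union (a small dark nucleus in a large bright field barely
// moves the union's sd, but blows its range).
static inline bool homogeneous(const RegStat &s, double range_cap) {
  return (s.mx - s.mn) <= range_cap;
}

// neighbor offsets in row-major scan order
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int nn = connectivity == 8 ? 8 : 4;
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * h);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % h, pc = p / h;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + (nn == 8 ? DR8[k] : dr4[k]);
          int qc = pc + (nn == 8 ? DC8[k] : dc4[k]);
          if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * h);
          }
        }
      }
    }
  }
  return lab;
}

// Seeded adaptive region growing. Seeds on a regular grid (row-major order),
// then any still-unassigned pixel becomes a new seed. A region admits an
// adjacent pixel q when |I(q) - running mean| <= k * max(running sd, 1).
// Breadth-first; the frontier queue is FIFO with neighbors pushed in
// row-major relative order, which fixes the growth order deterministically.
// [[Rcpp::export]]
IntegerMatrix region_grow_cpp(NumericMatrix img, double k, int spacing,
                              int connectivity) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix lab(h, w);
  int nn = connectivity == 8 ? 8 : 4;
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int next = 0;

  std::vector<int> seeds;
  int half = spacing / 2;
  for (int r = half; r < h; r += spacing)
    for (int c = half; c < w; c += spacing)
      seeds.push_back(r + c * h);
  // fall-through seeds: every pixel in row-major order
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c)
      seeds.push_back(r + c * h);

  std::queue<int> q;
  for (size_t si = 0; si < seeds.size(); ++si) {
    int s = seeds[si];
    int sr = s % h, sc = s / h;
    if (lab(sr, sc) != 0) continue;
    ++next;
    RegStat st;
    lab(sr, sc) = next;
    st.add(img(sr, sc));
    while (!q.empty()) q.pop();
    q.push(s);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int pr = p % h, pc = p / h;
      double thr = k * std::max(st.sd(), 1.0);
      for (int t = 0; t < nn; ++t) {
        int qr = pr + (nn == 8 ? DR8[t] : dr4[t]);
        int qc = pc + (nn == 8 ? DC8[t] : dc4[t]);
        if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
        if (lab(qr, qc) != 0) continue;
        if (std::fabs(img(qr, qc) - st.mean()) <= thr) {
          lab(qr, qc) = next;
          st.add(img(qr, qc));
          q.push(qr + qc * h);
          thr = k * std::max(st.sd(), 1.0);
        }
      }
    }
  }
  return lab;
}

static std::vector<RegStat> collect_stats(const IntegerMatrix &lab,
                                          const NumericMatrix &img, int nreg) {
  std::vector<RegStat> st(nreg + 1);
  int h = lab.nrow(), w = lab.ncol();
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      st[lab(r, c)].add(img(r, c));
  return st;
}

// Repair pass: any region whose intensity range exceeds range_cap has its
// extreme pixels (deviation > range_cap / 2 from the region mean) split
// off; split pixels and the remainder are relabeled as connected
// components. After one strip the remainder lies inside a band of width
// range_cap around the old mean, so its range satisfies the cap; stripped
// components are re-checked on later iterations.
// [[Rcpp::export]]
IntegerMatrix region_repair_cpp(IntegerMatrix lab0, NumericMatrix img,
                                double k, double range_cap, int connectivity,
                                int max_iter) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix lab = clone(lab0);
  for (int iter = 0; iter < max_iter; ++iter) {
    int nreg = 0;
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r)
        if (lab(r, c) > nreg) nreg = lab(r, c);
    std::vector<RegStat> st = collect_stats(lab, img, nreg);
    bool any = false;
    IntegerMatrix strip(h, w); // 1 = pixel stripped from its region
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        int g = lab(r, c);
        if (g == 0) continue;
        if (homogeneous(st[g], range_cap)) continue;
        double dev = std::fabs(img(r, c) - st[g].mean());
        if (dev > range_cap / 2.0) {
          strip(r, c) = 1;
          any = true;
        }
      }
    }
    if (!any) break;
    // relabel: components of (region, stripped?) cells get fresh labels
    IntegerMatrix key(h, w);
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r)
        key(r, c) = lab(r, c) * 2 + strip(r, c);
    // connected components within identical keys
    IntegerMatrix out(h, w);
    int nn = connectivity == 8 ? 8 : 4;
    const int dr4[4] = {-1, 0, 0, 1};
    const int dc4[4] = {0, -1, 1, 0};
    int next = 0;
    std::vector<int> stack;
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        if (out(r, c) != 0) continue;
        ++next;
        int kk = key(r, c);
        stack.clear();
        stack.push_back(r + c * h);
        out(r, c) = next;
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int pr = p % h, pc = p / h;
          for (int t = 0; t < nn; ++t) {
            int qr = pr + (nn == 8 ? DR8[t] : dr4[t]);
            int qc = pc + (nn == 8 ? DC8[t] : dc4[t]);
            if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
            if (out(qr, qc) == 0 && key(qr, qc) == kk) {
              out(qr, qc) = next;
              stack.push_back(qr + qc * h);
            }
          }
        }
      }
    }
    lab = out;
  }
  return lab;
}

// Merge pass: repeatedly merge adjacent regions whose union still satisfies
// the homogeneity predicate (range <= range_cap), sweeping pairs in sorted label
// order until a fixpoint. Union-find keeps the pass near-linear.
// [[Rcpp::export]]
IntegerMatrix region_merge_cpp(IntegerMatrix lab0, NumericMatrix img,
                               double range_cap, int connectivity) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix lab = clone(lab0);
  int nn = connectivity == 8 ? 8 : 4;
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};

  bool changed = true;
  while (changed) {
    changed = false;
    int nreg = 0;
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r)
        if (lab(r, c) > nreg) nreg = lab(r, c);
    std::vector<RegStat> st = collect_stats(lab, img, nreg);
    // adjacency pairs (a < b), deduplicated via sorted vector
    std::vector<long long> pairs;
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        int a = lab(r, c);
        for (int t = 0; t < nn; ++t) {
          int qr = r + (nn == 8 ? DR8[t] : dr4[t]);
          int qc = c + (nn == 8 ? DC8[t] : dc4[t]);
          if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
          int b = lab(qr, qc);
          if (a == b || a == 0 || b == 0) continue;
          int lo = std::min(a, b), hi = std::max(a, b);
          pairs.push_back((long long)lo * (nreg + 1) + hi);
        }
      }
    }
    std::sort(pairs.begin(), pairs.end());
    pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());

    std::vector<int> parent(nreg + 1);
    for (int i = 0; i <= nreg; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    for (size_t i = 0; i < pairs.size(); ++i) {
      int lo = (int)(pairs[i] / (nreg + 1));
      int hi = (int)(pairs[i] % (nreg + 1));
      int ra = find(lo), rb = find(hi);
      if (ra == rb) continue;
      RegStat u = st[ra].merged(st[rb]);
      if (homogeneous(u, range_cap)) {
        int keep = std::min(ra, rb), drop = std::max(ra, rb);
        parent[drop] = keep;
        st[keep] = u;
        changed = true;
      }
    }
    if (changed) {
      // apply union-find and compact labels to 1..m
      std::vector<int> remap(nreg + 1, 0);
      int m = 0;
      for (int g = 1; g <= nreg; ++g) {
        int root = find(g);
        if (remap[root] == 0) remap[root] = ++m;
      }
      for (int c = 0; c < w; ++c)
        for (int r = 0; r < h; ++r)
          if (lab(r, c) > 0) lab(r, c) = remap[find(lab(r, c))];
    }
  }
  return lab;
}

// Per-region summary used by select_roi and the condition checks:
// columns n, mean, sd, min, max.
// [[Rcpp::export]]
NumericMatrix region_stats_cpp(IntegerMatrix lab, NumericMatrix img) {
  int h = lab.nrow(), w = lab.ncol();
  int nreg = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (lab(r, c) > nreg) nreg = lab(r, c);
  std::vector<RegStat> st = collect_stats(lab, img, nreg);
  NumericMatrix out(nreg, 5);
  for (int g = 1; g <= nreg; ++g) {
    out(g - 1, 0) = st[g].n;
    out(g - 1, 1) = st[g].n > 0 ? st[g].mean() : NA_REAL;
    out(g - 1, 2) = st[g].sd();
    out(g - 1, 3) = st[g].mn;
    out(g - 1, 4) = st[g].mx;
  }
  return out;
}

// 24-neighbor local binary pattern codes on a 5x5 square neighborhood.
// Neighbors enumerated clockwise from the top-left corner: first the outer
// 5x5 ring (16 pixels), then the inner 3x3 ring (8 pixels). Bit p weight 2^p.
// Returns -1 outside the ROI or where the neighborhood leaves the image.
// [[Rcpp::export]]
NumericMatrix lbp_codes_cpp(NumericMatrix img, IntegerMatrix roi) {
  int h = img.nrow(), w = img.ncol();
  // clockwise outer ring from (-2,-2)
  static const int oR[16] = {-2,-2,-2,-2,-2,-1, 0, 1, 2, 2, 2, 2, 2, 1, 0,-1};
  static const int oC[16] = {-2,-1, 0, 1, 2, 2, 2, 2, 2, 1, 0,-1,-2,-2,-2,-2};
  // clockwise inner ring from (-1,-1)
  static const int iR[8] = {-1,-1,-1, 0, 1, 1, 1, 0};
  static const int iC[8] = {-1, 0, 1, 1, 1, 0,-1,-1};
  NumericMatrix codes(h, w);
  std::fill(codes.begin(), codes.end(), -1.0);
  for (int c = 2; c < w - 2; ++c) {
    for (int r = 2; r < h - 2; ++r) {
      if (roi(r, c) == 0) continue;
      double gc = img(r, c), code = 0, bit = 1;
      for (int p = 0; p < 16; ++p) {
        if (img(r + oR[p], c + oC[p]) - gc >= 0) code += bit;
        bit *= 2;
      }
      for (int p = 0; p < 8; ++p) {
        if (img(r + iR[p], c + iC[p]) - gc >= 0) code += bit;
        bit *= 2;
      }
      codes(r, c) = code;
    }
  }
  return codes;
}
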