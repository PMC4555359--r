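// Reliability-guided congruent phase unwrapping.
//
// Edges of the 8-neighbor pixel graph are weighted by second differences of
// the wrapped phase taken along the edge direction (a smooth wrapped gradient
// in that direction is trusted), sorted, and merged with a union-find whose
// nodes carry integer 2*pi offsets. An optional congruent relaxation pass
// then lowers local 2*pi inconsistencies pixel by pixel.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

static inline double wrapd(double x) {
  return x - TWOPI * std::ceil(x / TWOPI - 0.5);
}

struct DSU {
  std::vector<int> parent, rank_;
  std::vector<long long> pot; // 2*pi multiples relative to parent
  explicit DSU(int n) : parent(n), rank_(n, 0), pot(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  // returns root; off receives offset of x relative to root
  int find(int x, long long &off) {
    std::vector<int> path;
    while (parent[x] != x) { path.push_back(x); x = parent[x]; }
    long long run = 0;
    for (int i = (int)path.size() - 1; i >= 0; --i) {
      run += pot[path[i]];
      pot[path[i]] = run;
      parent[path[i]] = x;
    }
    off = path.empty() ? 0 : pot[path[0]];
    return x;
  }
};

// [[Rcpp::export(name = ".mst_unwrap_cpp")]]
NumericMatrix mst_unwrap_cpp(NumericMatrix w, int relax_sweeps = 20) {
  const int n1 = w.nrow(), n2 = w.ncol();
  const int N = n1 * n2;
  const double *wp = REAL(w);

  auto at = [&](int i, int j) { return wp[i + (long)j * n1]; };
  auto id = [&](int i, int j) { return i + j * n1; };

  std::vector<int> ea, eb;
  std::vector<double> wt;
  ea.reserve(4L * N); eb.reserve(4L * N); wt.reserve(4L * N);

  // horizontal (step in i)
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i + 1 < n1; ++i) {
      double d = wrapd(at(i + 1, j) - at(i, j));
      double dp = (i > 0) ? wrapd(at(i, j) - at(i - 1, j)) : d;
      double dn = (i + 2 < n1) ? wrapd(at(i + 2, j) - at(i + 1, j)) : d;
      ea.push_back(id(i, j)); eb.push_back(id(i + 1, j));
      wt.push_back(std::fabs(d - dp) + std::fabs(dn - d));
    }
  // vertical (step in j)
  for (int j = 0; j + 1 < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double d = wrapd(at(i, j + 1) - at(i, j));
      double dp = (j > 0) ? wrapd(at(i, j) - at(i, j - 1)) : d;
      double dn = (j + 2 < n2) ? wrapd(at(i, j + 2) - at(i, j + 1)) : d;
      ea.push_back(id(i, j)); eb.push_back(id(i, j + 1));
      wt.push_back(std::fabs(d - dp) + std::fabs(dn - d));
    }
  // diagonal (+1, +1)
  for (int j = 0; j + 1 < n2; ++j)
    for (int i = 0; i + 1 < n1; ++i) {
      double d = wrapd(at(i + 1, j + 1) - at(i, j));
      double dp = (i > 0 && j > 0) ? wrapd(at(i, j) - at(i - 1, j - 1)) : d;
      double dn = (i + 2 < n1 && j + 2 < n2)
                      ? wrapd(at(i + 2, j + 2) - at(i + 1, j + 1)) : d;
      ea.push_back(id(i, j)); eb.push_back(id(i + 1, j + 1));
      wt.push_back(std::fabs(d - dp) + std::fabs(dn - d));
    }
  // anti-diagonal (-1, +1): a = (i+1, j), b = (i, j+1)
  for (int j = 0; j + 1 < n2; ++j)
    for (int i = 0; i + 1 < n1; ++i) {
      double d = wrapd(at(i, j + 1) - at(i + 1, j));
      double dp = (i + 2 < n1 && j > 0)
                      ? wrapd(at(i + 1, j) - at(i + 2, j - 1)) : d;
      double dn = (i > 0 && j + 2 < n2)
                      ? wrapd(at(i - 1, j + 2) - at(i, j + 1)) : d;
      ea.push_back(id(i + 1, j)); eb.push_back(id(i, j + 1));
      wt.push_back(std::fabs(d - dp) + std::fabs(dn - d));
    }

  std::vector<int> ord(wt.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return wt[a] < wt[b]; });

  DSU dsu(N);
  int merges = 0;
  for (size_t q = 0; q < ord.size() && merges < N - 1; ++q) {
    int e = ord[q];
    long long offa, offb;
    int ra = dsu.find(ea[e], offa);
    int rb = dsu.find(eb[e], offb);
    if (ra == rb) continue;
    double draw = wp[eb[e]] - wp[ea[e]];
    long long k = llround((wrapd(draw) - draw) / TWOPI); // k_b - k_a
    if (dsu.rank_[ra] >= dsu.rank_[rb]) {
      dsu.pot[rb] = offa + k - offb;
      dsu.parent[rb] = ra;
      if (dsu.rank_[ra] == dsu.rank_[rb]) dsu.rank_[ra]++;
    } else {
      dsu.pot[ra] = offb - k - offa;
      dsu.parent[ra] = rb;
    }
    ++merges;
  }

  NumericMatrix u(n1, n2);
  for (int x = 0; x < N; ++x) {
    long long off;
    dsu.find(x, off);
    u[x] = wp[x] + TWOPI * (double)off;
  }

  // congruent relaxation: move pixels by multiples of 2*pi when that lowers
  // the L1 mismatch with their 4-neighborhood
  for (int sweep = 0; sweep < relax_sweeps; ++sweep) {
    int changed = 0;
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double cur = u(i, j);
        double best = cur, bestcost = 0;
        bool first = true;
        for (int s = -2; s <= 2; ++s) {
          double v = cur + TWOPI * s;
          double cost = 0;
          if (i > 0) cost += std::fabs(v - u(i - 1, j));
          if (i + 1 < n1) cost += std::fabs(v - u(i + 1, j));
          if (j > 0) cost += std::fabs(v - u(i, j - 1));
          if (j + 1 < n2) cost += std::fabs(v - u(i, j + 1));
          if (first || cost < bestcost - 1e-12) {
            bestcost = cost; best = v; first = false;
          }
        }
        if (best != cur) { u(i, j) = best; ++changed; }
      }
    if (!changed) break;
  }
  return u;
}
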