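#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive minimum-wss partitioning for small panels.
//
// Enumerates every set partition of n points into at most k non-empty
// clusters via restricted-growth strings, visited in lexicographic order of
// the canonical assignment vector. Adding a point x to a cluster with m
// members and mean mu increases that cluster's sum of squares by
// m/(m+1) * ||x - mu||^2, so the running objective is a valid lower bound
// and branches with curW >= bestW can be pruned. Only strict improvements
// replace the incumbent, hence ties resolve to the lexicographically
// smallest assignment over the (pre-sorted) input order.

namespace {

struct Search {
  int n, k, d;
  const double *x;              // n x d, column-major
  std::vector<double> sum;      // k x d running cluster sums
  std::vector<int> cnt;
  std::vector<int> cur, best;
  double curW, bestW;

  void descend(int i, int max_used) {
    if (i == n) {
      if (curW < bestW) { bestW = curW; best = cur; }
      return;
    }
    int lim = std::min(max_used + 1, k - 1);
    for (int c = 0; c <= lim; ++c) {
      double delta = 0.0;
      int m = cnt[c];
      if (m > 0) {
        double s2 = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = x[i + (size_t)j * n] - sum[c + (size_t)j * k] / m;
          s2 += diff * diff;
        }
        delta = s2 * m / (m + 1.0);
      }
      if (curW + delta >= bestW) continue;
      cnt[c]++;
      for (int j = 0; j < d; ++j) sum[c + (size_t)j * k] += x[i + (size_t)j * n];
      curW += delta;
      cur[i] = c;
      descend(i + 1, std::max(max_used, c));
      curW -= delta;
      cnt[c]--;
      for (int j = 0; j < d; ++j) sum[c + (size_t)j * k] -= x[i + (size_t)j * n];
    }
  }
};

} // namespace

// [[Rcpp::export]]
List exact_kmeans_cpp(NumericMatrix X, int k) {
  Search s;
  s.n = X.nrow();
  s.k = k;
  s.d = X.ncol();
  if (s.n < 1) stop("need at least one point");
  if (k < 1 || k > s.n) stop("k must be between 1 and the number of points");
  s.x = REAL(X);
  s.sum.assign((size_t)s.k * s.d, 0.0);
  s.cnt.assign(s.k, 0);
  s.cur.assign(s.n, 0);
  s.best.assign(s.n, 0);
  s.curW = 0.0;
  s.bestW = R_PosInf;
  s.descend(0, -1);

  IntegerVector assign(s.n);
  for (int i = 0; i < s.n; ++i) assign[i] = s.best[i] + 1;
  return List::create(Named("assignment") = assign,
                      Named("wss") = s.bestW);
}
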