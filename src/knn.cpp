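#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Brute-force k nearest neighbors among n points, self excluded.
// Ties in distance are broken by ascending point index so the result is
// fully deterministic.  O(n^2) distance evaluations with an O(n log k)
// partial-selection per query; fine for whole-slide cell tables (n ~ 1e5).
// [[Rcpp::export(name = ".knn_brute_cpp")]]
List knn_brute_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<std::pair<double, int>> cand;
  cand.reserve(n - 1);
  for (int i = 0; i < n; ++i) {
    cand.clear();
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - xi, dy = y[j] - yi;
      cand.emplace_back(dx * dx + dy * dy, j);
    }
    // pair comparison = (distance, index) lexicographic: the tie-break
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = cand[m].second + 1;  // 1-based for R
      dist(i, m) = std::sqrt(cand[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// For each query point, minimum Euclidean distance to any target point,
// excluding identical indices (used when the query set is a subset of the
// target set).  query_of / target_of are 1-based row indices into the same
// cell table; -1 in the output marks "no eligible target".
// [[Rcpp::export(name = ".nearest_dist_cpp")]]
NumericVector nearest_dist_cpp(NumericVector x, NumericVector y,
                               IntegerVector query_of, IntegerVector target_of) {
  const int nq = query_of.size(), nt = target_of.size();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const int qi = query_of[i] - 1;
    const double xi = x[qi], yi = y[qi];
    double best = -1.0;
    for (int j = 0; j < nt; ++j) {
      const int tj = target_of[j] - 1;
      if (tj == qi) continue;
      const double dx = x[tj] - xi, dy = y[tj] - yi;
      const double d2 = dx * dx + dy * dy;
      if (best < 0.0 || d2 < best) best = d2;
    }
    out[i] = best < 0.0 ? NA_REAL : std::sqrt(best);
  }
  return out;
}
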