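#include <Rcpp.h>
using namespace Rcpp;

// Exact dynamic-time-warping distance with absolute-difference local cost,
// full window, unit steps. Two-row dynamic program, O(n*m) time, O(m) space.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<double> prev(m), cur(m);
  prev[0] = std::abs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = best + std::abs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Lower-triangle pairwise DTW distances for a list of equal-length
// profiles, returned as a full symmetric matrix.
// [[Rcpp::export(name = ".dtw_pairwise")]]
NumericMatrix dtw_pairwise(List profiles) {
  const int n = profiles.size();
  NumericMatrix d(n, n);
  std::vector<NumericVector> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<NumericVector>(profiles[i]);
  for (int i = 1; i < n; ++i)
    for (int j = 0; j < i; ++j)
      d(i, j) = d(j, i) = dtw_cost(xs[i], xs[j]);
  return d;
}
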