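#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic-time-warping distance with absolute-difference local
// cost and symmetric steps (match / insert / delete), no band constraint.
// Two-row rolling dynamic programme, O(n*m) time, O(m) memory.
static double dtw_core(const NumericVector& a, const NumericVector& b) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m), cur(m);
  prev[0] = std::abs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = best + std::abs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector a, NumericVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("DTW is undefined for empty series");
  return dtw_core(a, b);
}

// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List series) {
  const int n = series.size();
  NumericMatrix d(n, n);
  std::vector<NumericVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<NumericVector>(series[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = dtw_core(s[i], s[j]);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
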