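#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping cost between two 1-D contours with absolute-difference
// local cost and symmetric steps; returns the total optimal-path cost
// (normalization to (n + m) happens on the R side).
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double cost = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
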