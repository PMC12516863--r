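#include <Rcpp.h>
using namespace Rcpp;

// Exact brute-force k-nearest neighbors on 2-D coordinates.
// Ties in distance are broken by ascending point index, so callers that
// order points by cell id get the documented deterministic tie rule.
// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (k <= 0) stop("k must be positive");
  if (n < 2) stop("need at least 2 points");
  int kk = std::min(k, n - 1);
  IntegerMatrix out(n, kk);
  std::vector<double> bd(kk);
  std::vector<int> bi(kk);
  for (int i = 0; i < n; ++i) {
    int m = 0; // current number of stored neighbors
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d = dx * dx + dy * dy;
      if (m == kk && (d > bd[kk - 1] || (d == bd[kk - 1] && j > bi[kk - 1])))
        continue;
      // insertion into the sorted (distance, index) buffer
      int pos = (m < kk) ? m : kk - 1;
      while (pos > 0 && (bd[pos - 1] > d || (bd[pos - 1] == d && bi[pos - 1] > j))) {
        bd[pos] = bd[pos - 1];
        bi[pos] = bi[pos - 1];
        --pos;
      }
      bd[pos] = d;
      bi[pos] = j;
      if (m < kk) ++m;
    }
    for (int c = 0; c < kk; ++c) out(i, c) = bi[c] + 1;
  }
  return out;
}

// For each query point, squared-distance-minimizing reference point.
// Returns the Euclidean distance to the nearest reference.
// [[Rcpp::export(name = ".nearest_cross")]]
NumericVector nearest_cross(NumericVector qx, NumericVector qy,
                            NumericVector rx, NumericVector ry) {
  int n = qx.size(), m = rx.size();
  NumericVector out(n);
  if (m == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = rx[j] - qx[i], dy = ry[j] - qy[i];
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
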