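#include <Rcpp.h>
using namespace Rcpp;

// Bin counts of pairwise spike-time differences u - t (u in y, t in x)
// into 2K+1 bins of width dt centred at k*dt, k = -K..K, where
// K = round(tau_max / dt). Bin k covers [k*dt - dt/2, k*dt + dt/2).
// Both trains must be sorted ascending; two-pointer sweep, O(Nx + pairs).
// [[Rcpp::export]]
IntegerVector cc_counts(NumericVector x, NumericVector y,
                        double tau_max, double dt) {
  if (dt <= 0) stop("dt must be positive");
  int K = (int)std::floor(tau_max / dt + 0.5);
  int nb = 2 * K + 1;
  IntegerVector counts(nb);
  double lo = -(K + 0.5) * dt, hi = (K + 0.5) * dt;
  int ny = y.size(), j0 = 0;
  for (int i = 0; i < x.size(); ++i) {
    double t = x[i];
    while (j0 < ny && y[j0] - t < lo) ++j0;
    for (int j = j0; j < ny; ++j) {
      double d = y[j] - t;
      if (d >= hi) break;
      int k = (int)std::floor(d / dt + 0.5) + K;
      if (k >= 0 && k < nb) ++counts[k];
    }
  }
  return counts;
}

// Peak of the correlogram of (x, y) without materialising the histogram
// in R: returns (max count, lag index of max with smallest |lag| and
// positive-lag preference on ties). Used in the dithering null loop.
// [[Rcpp::export]]
List cc_peak_counts(NumericVector x, NumericVector y,
                    double tau_max, double dt) {
  IntegerVector counts = cc_counts(x, y, tau_max, dt);
  int K = (counts.size() - 1) / 2;
  int best = -1, bestc = -1;
  for (int k = 0; k < counts.size(); ++k) {
    int lag = k - K;
    if (counts[k] > bestc) { bestc = counts[k]; best = k; }
    else if (counts[k] == bestc && best >= 0) {
      int blag = best - K;
      if (std::abs(lag) < std::abs(blag) ||
          (std::abs(lag) == std::abs(blag) && lag > blag)) {
        best = k;
      }
    }
  }
  return List::create(_["count"] = bestc, _["lag_index"] = best - K);
}
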