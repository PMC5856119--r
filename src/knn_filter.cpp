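#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Brute-force K-nearest-neighbor mean of probability vectors in a small
// (3-D) feature space. Each point's own distance is forced below any real
// distance so the pixel itself is always among its K neighbors (K = 1 is
// the identity); remaining ties resolve by point index.
// [[Rcpp::export]]
NumericMatrix knn_mean_probs(const NumericMatrix& feats,
                             const NumericMatrix& probs, const int K) {
  const int n = feats.nrow();
  const int d = feats.ncol();
  const int nc = probs.ncol();
  if (K < 1 || K > n) stop("K must lie in [1, n]");
  NumericMatrix out(n, nc);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = feats(i, k) - feats(j, k);
        d2 += diff * diff;
      }
      cand[j] = std::make_pair(j == i ? -1.0 : d2, j);
    }
    std::nth_element(cand.begin(), cand.begin() + (K - 1), cand.end());
    for (int m = 0; m < K; ++m) {
      const int j = cand[m].second;
      for (int c = 0; c < nc; ++c) out(i, c) += probs(j, c);
    }
    for (int c = 0; c < nc; ++c) out(i, c) /= K;
  }
  return out;
}
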