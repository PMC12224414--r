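#include <Rcpp.h>
using namespace Rcpp;

// Euclidean projection of z onto the nonincreasing cone
// { x : x[0] >= x[1] >= ... >= x[m-1] } by pool-adjacent-violators.
// Runs in O(m) amortized: blocks are merged at most m-1 times.
// [[Rcpp::export]]
NumericVector pava_nonincreasing(NumericVector z) {
  int m = z.size();
  NumericVector out(m);
  if (m == 0) return out;
  // block stacks: mean, weight (=length), end index
  std::vector<double> mean(m), wt(m);
  std::vector<int> last(m);
  int nb = 0;
  for (int i = 0; i < m; ++i) {
    mean[nb] = z[i];
    wt[nb] = 1.0;
    last[nb] = i;
    ++nb;
    // a violation of nonincreasing order is a later block with larger mean
    while (nb > 1 && mean[nb - 2] < mean[nb - 1]) {
      double w = wt[nb - 2] + wt[nb - 1];
      mean[nb - 2] = (wt[nb - 2] * mean[nb - 2] + wt[nb - 1] * mean[nb - 1]) / w;
      wt[nb - 2] = w;
      last[nb - 2] = last[nb - 1];
      --nb;
    }
  }
  int i = 0;
  for (int b = 0; b < nb; ++b)
    for (; i <= last[b]; ++i) out[i] = mean[b];
  return out;
}
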