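#include <Rcpp.h>
using namespace Rcpp;

// Maximum-penalised-likelihood state path for one chromosome of one cell.
// logem: n x K per-read log emission probabilities; penalty: cost per state
// change. Ties prefer staying in the current state, then the lower state
// index (state order is fixed by the caller).
// [[Rcpp::export]]
IntegerVector viterbi_states(NumericMatrix logem, double penalty) {
  const int n = logem.nrow(), K = logem.ncol();
  IntegerVector path(n);
  if (n == 0) return path;
  NumericMatrix score(n, K);
  IntegerMatrix back(n, K);
  for (int k = 0; k < K; ++k) score(0, k) = logem(0, k);
  for (int i = 1; i < n; ++i) {
    for (int k = 0; k < K; ++k) {
      double best = score(i - 1, k);   // stay
      int arg = k;
      for (int j = 0; j < K; ++j) {
        if (j == k) continue;
        double v = score(i - 1, j) - penalty;
        if (v > best + 1e-12) { best = v; arg = j; }
      }
      score(i, k) = best + logem(i, k);
      back(i, k) = arg;
    }
  }
  int arg = 0;
  double best = score(n - 1, 0);
  for (int k = 1; k < K; ++k)
    if (score(n - 1, k) > best + 1e-12) { best = score(n - 1, k); arg = k; }
  path[n - 1] = arg;
  for (int i = n - 1; i > 0; --i) path[i - 1] = back(i, path[i]);
  for (int i = 0; i < n; ++i) path[i] += 1;
  return path;
}
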