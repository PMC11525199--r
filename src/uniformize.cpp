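#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Uniformization recursion for the truncated master equation:
// acc = sum_k dpois(k; lt) * P^k v0, with P given in compressed sparse
// column form (slots of a dgCMatrix, column j = outgoing state). Keeping the
// whole Poisson-weighted power series in C++ avoids per-iteration dispatch
// and allocation for the many sparse matrix-vector products.
// [[Rcpp::export]]
NumericVector uniformize_cpp(IntegerVector Pi, IntegerVector Pp,
                             NumericVector Px, NumericVector v0, double lt) {
  const int n = v0.size();
  if (lt <= 0.0) return clone(v0);
  std::vector<double> v(v0.begin(), v0.end()), nv(n), acc(n, 0.0);
  const int K = static_cast<int>(R::qpois(1.0 - 1e-13, lt, 1, 0)) + 2;
  double w = R::dpois(0.0, lt, 0);
  for (int i = 0; i < n; ++i) acc[i] = w * v[i];
  for (int k = 1; k <= K; ++k) {
    std::fill(nv.begin(), nv.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double vj = v[j];
      if (vj == 0.0) continue;
      for (int idx = Pp[j]; idx < Pp[j + 1]; ++idx)
        nv[Pi[idx]] += Px[idx] * vj;
    }
    v.swap(nv);
    w = R::dpois(static_cast<double>(k), lt, 0);
    if (w > 0.0 || k < lt)
      for (int i = 0; i < n; ++i) acc[i] += w * v[i];
  }
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (acc[i] < 0.0) acc[i] = 0.0;
    total += acc[i];
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = acc[i] / total;
  return out;
}
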