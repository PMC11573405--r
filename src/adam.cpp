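#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused in-place Adam update over one parameter block. The caller owns the
// p/m/v buffers exclusively (training-loop internals); mutating them in
// place avoids the temporary-allocation churn that dominates large updates
// in pure R.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double b1, double b2,
                         double eps, double c1, double c2) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("parameter/moment/gradient sizes differ");
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
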