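#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update over one parameter tensor. The caller owns
// p/m/v exclusively (training loop deep-copies at entry), so in-place
// mutation is safe and avoids per-step allocation of ~16M doubles.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector g, NumericVector m,
                         NumericVector v, double lr, double beta1,
                         double beta2, double eps, double bc1, double bc2) {
  R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_inplace: length mismatch");
  // p -= lr * (m/bc1) / (sqrt(v/bc2) + eps), with the bias corrections
  // hoisted out of the loop so each element costs one sqrt and one divide
  const double lr_c = lr / bc1;
  const double isq_bc2 = 1.0 / std::sqrt(bc2);
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + om1 * g[i];
    v[i] = beta2 * v[i] + om2 * g[i] * g[i];
    p[i] -= lr_c * m[i] / (std::sqrt(v[i]) * isq_bc2 + eps);
  }
}
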