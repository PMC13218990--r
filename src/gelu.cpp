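// tanh-approximation GELU, fused to avoid R-level temporaries on the
// (B*T) x (mlp_ratio*D) hidden activation.

#include <Rcpp.h>
using namespace Rcpp;

static const double C0 = 0.7978845608028654;  // sqrt(2/pi)
static const double C1 = 0.044715;

// [[Rcpp::export]]
List gelu_fwd_cpp(const NumericMatrix &x) {
  NumericMatrix y(x.nrow(), x.ncol()), t(x.nrow(), x.ncol());
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = x[i];
    const double th = std::tanh(C0 * (v + C1 * v * v * v));
    t[i] = th;
    y[i] = 0.5 * v * (1.0 + th);
  }
  return List::create(Named("y") = y, Named("t") = t);
}

// [[Rcpp::export]]
NumericMatrix gelu_grad_cpp(const NumericMatrix &x, const NumericMatrix &t) {
  NumericMatrix g(x.nrow(), x.ncol());
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = x[i], th = t[i];
    g[i] = 0.5 * (1.0 + th) +
      0.5 * v * (1.0 - th * th) * C0 * (1.0 + 3.0 * C1 * v * v);
  }
  return g;
}
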