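#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update over a list of parameter arrays. Gradients for
// weight-tagged parameters receive the L2 penalty term 2*lambda*p before the
// moment updates. Returns the post-update sum of squared weights (used for
// the regularized loss log without an extra pass over the parameters).
// [[Rcpp::export]]
double adam_step_inplace(List params, List grads, List m, List v,
                         LogicalVector is_weight, double lr, double beta1,
                         double beta2, double eps, int t, double lambda) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  double wns = 0.0;
  const int np = params.size();
  for (int k = 0; k < np; ++k) {
    NumericVector p = params[k];
    NumericVector g = grads[k];
    NumericVector mm = m[k];
    NumericVector vv = v[k];
    const bool w = is_weight[k];
    const R_xlen_t len = p.size();
    if (g.size() != len || mm.size() != len || vv.size() != len)
      stop("adam_step_inplace: length mismatch at parameter %d", k + 1);
    double *pp = REAL(p), *gg = REAL(g), *pm = REAL(mm), *pv = REAL(vv);
    for (R_xlen_t i = 0; i < len; ++i) {
      double gi = gg[i];
      if (w) gi += 2.0 * lambda * pp[i];
      pm[i] = beta1 * pm[i] + (1.0 - beta1) * gi;
      pv[i] = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
      const double mhat = pm[i] / bc1;
      const double vhat = pv[i] / bc2;
      pp[i] -= lr * mhat / (std::sqrt(vhat) + eps);
      if (w) wns += pp[i] * pp[i];
    }
  }
  return wns;
}
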