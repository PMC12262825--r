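#include <Rcpp.h>
using namespace Rcpp;

// Negative Poisson log-likelihood (up to the log(n!) constant) and its
// gradient for a one-hot additive model: eta_t = sum_v beta[off_v + idx(t,v)],
// r_t = exp(eta_t), nll = sum_t (r_t - n_t * eta_t).
// idx is 1-based; offsets give each variable's position in beta.
// [[Rcpp::export]]
List glm_nll_grad(NumericVector beta, IntegerMatrix idx, NumericVector n,
                  IntegerVector offsets) {
  const int T = idx.nrow(), V = idx.ncol();
  NumericVector grad(beta.size());
  double nll = 0.0;
  for (int t = 0; t < T; ++t) {
    double eta = 0.0;
    for (int v = 0; v < V; ++v) eta += beta[offsets[v] + idx(t, v) - 1];
    double r = std::exp(eta);
    nll += r - n[t] * eta;
    double g = r - n[t];
    for (int v = 0; v < V; ++v) grad[offsets[v] + idx(t, v) - 1] += g;
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// Linear predictor for a variable subset (columns of idx), 1-based indices.
// [[Rcpp::export]]
NumericVector glm_eta(NumericVector beta, IntegerMatrix idx,
                      IntegerVector offsets) {
  const int T = idx.nrow(), V = idx.ncol();
  NumericVector eta(T);
  for (int t = 0; t < T; ++t) {
    double e = 0.0;
    for (int v = 0; v < V; ++v) e += beta[offsets[v] + idx(t, v) - 1];
    eta[t] = e;
  }
  return eta;
}
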