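// Profiled REML objective for the Gaussian mixed model.
//
// -2 * restricted log-likelihood (up to a constant) of
// y = X alpha + b + e, profiled over alpha and sigma2, as a function of the
// variance ratios delta_k in H = I + sum_k delta_k Psi_k. One evaluation
// costs one Cholesky of the n x n matrix H; this is the inner loop of
// fit_null_lmm(), so it avoids the copies an R implementation would make.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
double reml_obj_cpp(const arma::vec& delta, const arma::vec& y,
                    const arma::mat& X, const Rcpp::List& psis) {
  const uword n = y.n_elem, q = X.n_cols;
  mat H(n, n, fill::zeros);
  for (R_xlen_t k = 0; k < psis.size(); ++k) {
    if (delta[k] == 0.0) continue;
    Rcpp::NumericMatrix Pk = psis[k];
    const mat P(Pk.begin(), n, n, false, true); // no-copy view
    H += delta[k] * P;
  }
  H.diag() += 1.0;

  mat L;
  if (!chol(L, H, "lower")) return R_PosInf;
  vec ys = solve(trimatl(L), y);
  mat Xs = solve(trimatl(L), X);
  mat XtHX = Xs.t() * Xs;
  mat cX;
  if (!chol(cX, XtHX, "lower")) return R_PosInf;
  vec Xty = Xs.t() * ys;
  vec alpha = solve(trimatu(cX.t()), solve(trimatl(cX), Xty));
  double rss = dot(ys, ys) - dot(Xty, alpha);
  if (!(rss > 0.0)) return R_PosInf;
  double sigma2 = rss / double(n - q);
  return double(n - q) * std::log(sigma2) + 2.0 * sum(log(L.diag())) +
         2.0 * sum(log(cX.diag()));
}
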