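// Summed annual multivariate-normal log-likelihood for the Gaussian
// distance-decay correlogram. Years sharing the same observed-population
// set are factored once; each year's log-density then costs one
// triangular solve.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double LOG2PI = 1.8378770664093454836;

// idx_list: per group, 1-based indices into the site order of `dist`
// y_list:   per group, matrix (n_i x T_g) of observed value vectors
// [[Rcpp::export]]
double panel_loglik_cpp(Rcpp::List idx_list, Rcpp::List y_list,
                        const arma::mat& dist,
                        double rho0, double rho_inf, double l) {
  const double denom = 2.0 * l * l;
  double ll = 0.0;
  int G = idx_list.size();
  for (int g = 0; g < G; ++g) {
    arma::uvec idx = Rcpp::as<arma::uvec>(idx_list[g]) - 1;
    arma::mat Y = Rcpp::as<arma::mat>(y_list[g]);
    const arma::uword n = idx.n_elem;
    arma::mat D = dist.submat(idx, idx);
    arma::mat S = rho_inf + (rho0 - rho_inf) * arma::exp(-arma::square(D) / denom);
    S.diag().ones();
    arma::mat L;
    if (!arma::chol(L, S, "lower")) {
      S.diag() += 1e-8;  // one jitter attempt, then give up
      if (!arma::chol(L, S, "lower")) return R_NegInf;
    }
    double logdet_half = arma::accu(arma::log(L.diag()));
    arma::mat Z = arma::solve(arma::trimatl(L), Y);
    double T = static_cast<double>(Y.n_cols);
    ll += -T * (logdet_half + 0.5 * n * LOG2PI)
          - 0.5 * arma::accu(arma::square(Z));
  }
  return ll;
}
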