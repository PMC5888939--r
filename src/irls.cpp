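// Newton-Raphson (IRLS) core for weighted logistic regression with offset.
// Called from fit_logistic(); the R wrapper owns rank-deficiency handling,
// input checking and the user-facing API.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double loglik(const vec& y, const vec& eta, const vec& w) {
  // sum w * (y * eta - log(1 + exp(eta))), computed stably
  vec softplus = eta;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    softplus[i] = (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::abs(e)));
  }
  return dot(w, y % eta - softplus);
}

// [[Rcpp::export(name = ".irls_fit")]]
Rcpp::List irls_fit(const arma::mat& x, const arma::vec& y,
                    const arma::vec& w, const arma::vec& offset,
                    const arma::vec& start, int max_iter, double tol) {
  const uword p = x.n_cols;
  vec beta = start;
  vec eta = x * beta + offset;
  vec mu = 1.0 / (1.0 + exp(-eta));
  double ll = loglik(y, eta, w);
  bool converged = false;
  bool singular = false;
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    vec wirls = w % mu % (1.0 - mu);
    vec score = x.t() * (w % (y - mu));
    mat xs = x.each_col() % sqrt(wirls);
    mat info = xs.t() * xs;  // symmetric rank-k update
    vec step;
    bool ok = solve(step, info, score, solve_opts::no_approx);
    if (!ok || !step.is_finite()) { singular = true; break; }
    // step-halving if the likelihood does not improve
    vec beta_new, eta_new, mu_new;
    double ll_new = 0.0;
    int sh = 0;
    while (true) {
      beta_new = beta + step;
      eta_new = x * beta_new + offset;
      mu_new = 1.0 / (1.0 + exp(-eta_new));
      ll_new = loglik(y, eta_new, w);
      if (ll_new >= ll - 1e-10 || sh >= 20) break;
      step /= 2.0;
      ++sh;
    }
    double delta = abs(beta_new - beta).max();
    beta = beta_new; eta = eta_new; mu = mu_new; ll = ll_new;
    if (delta < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("fitted") = mu,
    Rcpp::Named("eta") = eta,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("singular") = singular,
    Rcpp::Named("iterations") = iter);
}
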