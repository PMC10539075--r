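#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted Bernoulli quasi-log-likelihood sum w * [y log mu + (1-y) log(1-mu)]
static double qll(const vec& eta, const vec& y, const vec& w) {
  vec mu = 1.0 / (1.0 + exp(-eta));
  mu = clamp(mu, 1e-12, 1.0 - 1e-12);
  return accu(w % (y % log(mu) + (1.0 - y) % log(1.0 - mu)));
}

// Fisher-scoring / IRLS solver for the weighted logistic quasi-score
//   U(theta) = X' diag(w) (y - mu(theta)) = 0
// (independence working correlation, Bernoulli variance).  Step-halving
// guards against quasi-likelihood decreases.  Returns both the model-based
// covariance inv(X' diag(w v) X) and the robust sandwich
// inv(A) B inv(A) with B = X' diag(w^2 (y-mu)^2) X.
// [[Rcpp::export]]
Rcpp::List wgee_irls_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::vec& w, double tol, int max_iter,
                         const arma::vec& start) {
  const int p = X.n_cols;
  vec b = start;
  vec eta = X * b;
  double q0 = qll(eta, y, w);
  bool converged = false, singular = false;
  int iter = 0;
  double score_norm = datum::inf;

  for (iter = 0; iter < max_iter; ++iter) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec v = mu % (1.0 - mu);
    vec U = X.t() * (w % (y - mu));
    score_norm = norm(U, "inf");
    if (score_norm < tol) { converged = true; break; }
    mat A = X.t() * (X.each_col() % (w % v));
    vec step;
    if (!solve(step, A, U, solve_opts::no_approx)) { singular = true; break; }
    double fac = 1.0;
    bool moved = false;
    for (int h = 0; h < 30; ++h) {
      vec bn = b + fac * step;
      vec en = X * bn;
      double qn = qll(en, y, w);
      // relative tolerance: quasi-likelihood sums carry O(n * eps * |q|)
      // rounding noise, so demand no more than noise-level decrease
      if (std::isfinite(qn) && qn >= q0 - 1e-8 * (1.0 + std::fabs(q0))) {
        b = bn; eta = en; q0 = qn; moved = true; break;
      }
      fac *= 0.5;
    }
    if (!moved) break;  // no admissible step left
  }

  vec mu = 1.0 / (1.0 + exp(-eta));
  vec v = mu % (1.0 - mu);
  vec U = X.t() * (w % (y - mu));
  score_norm = norm(U, "inf");
  converged = converged || (score_norm < tol);

  mat A = X.t() * (X.each_col() % (w % v));
  vec r2 = square(w % (y - mu));
  mat B = X.t() * (X.each_col() % r2);
  mat Ainv(p, p, fill::value(datum::nan));
  mat Vrob(p, p, fill::value(datum::nan));
  mat Ai;
  if (inv_sympd(Ai, symmatu(A))) {
    Ainv = Ai;
    Vrob = Ai * B * Ai;
  } else {
    singular = true;
  }

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = b,
    Rcpp::Named("vcov_model") = Ainv,
    Rcpp::Named("vcov_robust") = Vrob,
    Rcpp::Named("fitted") = mu,
    Rcpp::Named("linear_predictors") = eta,
    Rcpp::Named("score") = U,
    Rcpp::Named("score_norm") = score_norm,
    Rcpp::Named("iter") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("singular") = singular,
    Rcpp::Named("quasi_loglik") = q0);
}
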