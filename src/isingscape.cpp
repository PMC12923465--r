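#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Glauber dynamics: per sweep, visit nodes in a fresh random order and
// resample each from its full conditional logistic(beta * (m_i + W_i . a)).
// Uses R's RNG so trajectories are reproducible via set.seed().
// [[Rcpp::export]]
List glauber_chain_cpp(NumericVector m, NumericMatrix W, double beta,
                       int sweeps, int burn_in, IntegerVector init,
                       bool record_states) {
  const int N = m.size();
  std::vector<int> a(init.begin(), init.end());
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  int nact = 0;
  for (int i = 0; i < N; ++i) nact += a[i];
  const int recorded = sweeps - burn_in;
  IntegerVector nrec(recorded);
  IntegerMatrix srec = record_states ? IntegerMatrix(recorded, N)
                                     : IntegerMatrix(0, 0);
  for (int s = 0; s < sweeps; ++s) {
    // Fisher-Yates shuffle of the visit order
    for (int k = N - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(order[k], order[j]);
    }
    for (int k = 0; k < N; ++k) {
      const int i = order[k];
      double field = m[i];
      for (int j = 0; j < N; ++j) field += W(i, j) * a[j];
      const double p = 1.0 / (1.0 + std::exp(-beta * field));
      const int v = (unif_rand() < p) ? 1 : 0;
      nact += v - a[i];
      a[i] = v;
    }
    if (s >= burn_in) {
      nrec[s - burn_in] = nact;
      if (record_states)
        for (int j = 0; j < N; ++j) srec(s - burn_in, j) = a[j];
    }
  }
  IntegerVector fin(N);
  for (int i = 0; i < N; ++i) fin[i] = a[i];
  return List::create(_["n"] = nrec, _["states"] = srec, _["final"] = fin);
}

// Newton iteration for (optionally ridge-penalized) logistic regression.
// X includes the intercept column first; the penalty lambda applies to all
// coefficients except the intercept. `w` are nonnegative case weights.
// Divergence (|coef| running away without a penalty) is reported, not fixed:
// it is the caller's signal of perfect separation.
// [[Rcpp::export]]
List irls_logistic_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::vec& w, double lambda,
                       int max_iter = 50, double tol = 1e-10) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec pen(p, arma::fill::value(lambda));
  pen(0) = 0.0;
  bool converged = false, diverged = false;
  for (int it = 0; it < max_iter; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-(X * beta)));
    mu = arma::clamp(mu, 1e-12, 1.0 - 1e-12);
    arma::vec grad = X.t() * (w % (y - mu)) - pen % beta;
    arma::vec wt = w % mu % (1.0 - mu);
    arma::mat hess = X.t() * (X.each_col() % wt) + arma::diagmat(pen);
    arma::vec step;
    if (!arma::solve(step, hess, grad, arma::solve_opts::no_approx)) {
      diverged = true;
      break;
    }
    beta += step;
    if (arma::abs(beta).max() > 30.0 && lambda <= 0.0) {
      diverged = true;
      break;
    }
    if (arma::abs(step).max() < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["coef"] = beta, _["converged"] = converged,
                      _["diverged"] = diverged);
}
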