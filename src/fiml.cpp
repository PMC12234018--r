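// FIML objective and analytic gradient for the one-factor model with a
// shared loading, computed from per-missingness-pattern sufficient
// statistics so each evaluation is O(#patterns), not O(n).
//
// Parameter vector theta = (lambda, m1, m2, m3, log r1, log r2, log r3).
// Model-implied moments for a pattern observing indices o:
//   mu_o, Sigma_o = lambda^2 * J + diag(r_o),  J = ones(k, k)
// Pattern stats: n (rows), s = colsums of observed values, C = X'X.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Negative log-likelihood summed over patterns. Returns a large value if a
// pattern covariance is numerically non-positive-definite.
// [[Rcpp::export]]
double fiml_nll_cpp(NumericVector theta, List stats) {
  const double lambda = theta[0];
  const double lam2 = lambda * lambda;
  arma::vec m(3), r(3);
  for (int j = 0; j < 3; ++j) {
    m[j] = theta[1 + j];
    r[j] = std::exp(theta[4 + j]);
  }
  double nll = 0.0;
  for (int p = 0; p < stats.size(); ++p) {
    List st = stats[p];
    IntegerVector obs = st["obs"];
    const double n = as<double>(st["n"]);
    arma::vec s = as<arma::vec>(st["s"]);
    arma::mat C = as<arma::mat>(st["C"]);
    const int k = obs.size();

    arma::mat Sigma(k, k);
    Sigma.fill(lam2);
    arma::vec mu(k);
    for (int i = 0; i < k; ++i) {
      const int oi = obs[i] - 1;
      Sigma(i, i) += r[oi];
      mu[i] = m[oi];
    }
    arma::mat A;
    if (!arma::inv_sympd(A, Sigma)) return 1e12;
    double ldet, sign;
    arma::log_det(ldet, sign, Sigma);
    if (sign <= 0.0) return 1e12;

    arma::vec As = A * s;
    arma::vec Amu = A * mu;
    const double trAC = arma::accu(A % C);
    nll += 0.5 * (n * (k * LOG2PI + ldet) + trAC -
                  2.0 * arma::dot(mu, As) + n * arma::dot(mu, Amu));
  }
  return nll;
}

// Gradient of the negative log-likelihood in the same parameterisation
// (residual variances on the log scale).
// [[Rcpp::export]]
NumericVector fiml_nll_grad_cpp(NumericVector theta, List stats) {
  const double lambda = theta[0];
  const double lam2 = lambda * lambda;
  arma::vec m(3), r(3);
  for (int j = 0; j < 3; ++j) {
    m[j] = theta[1 + j];
    r[j] = std::exp(theta[4 + j]);
  }
  double gl = 0.0;
  arma::vec gm(3, arma::fill::zeros), glr(3, arma::fill::zeros);

  for (int p = 0; p < stats.size(); ++p) {
    List st = stats[p];
    IntegerVector obs = st["obs"];
    const double n = as<double>(st["n"]);
    arma::vec s = as<arma::vec>(st["s"]);
    arma::mat C = as<arma::mat>(st["C"]);
    const int k = obs.size();

    arma::mat Sigma(k, k);
    Sigma.fill(lam2);
    arma::vec mu(k);
    for (int i = 0; i < k; ++i) {
      const int oi = obs[i] - 1;
      Sigma(i, i) += r[oi];
      mu[i] = m[oi];
    }
    arma::mat A;
    if (!arma::inv_sympd(A, Sigma)) {
      continue;  // objective already signalled non-PD with a large value
    }
    arma::vec As = A * s;
    arma::vec Amu = A * mu;

    // u = A 1;  u' S u with S = C - s mu' - mu s' + n mu mu'
    arma::vec u = arma::sum(A, 1);
    const double us = arma::dot(u, s);
    const double umu = arma::dot(u, mu);
    const double uSu = arma::as_scalar(u.t() * C * u) - 2.0 * us * umu +
                       n * umu * umu;
    gl += lambda * (n * arma::accu(A) - uSu);

    // d/d mu_o = -A s + n A mu
    for (int i = 0; i < k; ++i) {
      gm[obs[i] - 1] += -As[i] + n * Amu[i];
    }

    // d/d log r_j = 0.5 r_j (n A_jj - (A S A)_jj)
    for (int i = 0; i < k; ++i) {
      arma::vec a = A.col(i);
      const double as_ = arma::dot(a, s);
      const double amu = arma::dot(a, mu);
      const double aSa = arma::as_scalar(a.t() * C * a) - 2.0 * as_ * amu +
                         n * amu * amu;
      glr[obs[i] - 1] += 0.5 * r[obs[i] - 1] * (n * A(i, i) - aSa);
    }
  }

  NumericVector out(7);
  out[0] = gl;
  for (int j = 0; j < 3; ++j) {
    out[1 + j] = gm[j];
    out[4 + j] = glr[j];
  }
  return out;
}
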