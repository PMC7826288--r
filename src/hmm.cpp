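#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a 2-state Gaussian-emission HMM with a
// common emission SD. Returns the log-likelihood, the posterior state
// probabilities (gamma) and the summed transition posteriors (xi).
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector mu, double sigma,
                          NumericMatrix A, NumericVector init) {
  const int n = x.size();
  NumericMatrix b(n, 2);
  const double c1 = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < 2; ++j) {
      double z = (x[t] - mu[j]) / sigma;
      b(t, j) = c1 * std::exp(-0.5 * z * z) + 1e-300;
    }
  }
  NumericMatrix alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericVector scale(n);
  for (int j = 0; j < 2; ++j) alpha(0, j) = init[j] * b(0, j);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= scale[0];
  alpha(0, 1) /= scale[0];
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < 2; ++j)
      alpha(t, j) = (alpha(t - 1, 0) * A(0, j) + alpha(t - 1, 1) * A(1, j)) * b(t, j);
    scale[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= scale[t];
    alpha(t, 1) /= scale[t];
  }
  beta(n - 1, 0) = 1.0;
  beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < 2; ++i) {
      beta(t, i) = (A(i, 0) * b(t + 1, 0) * beta(t + 1, 0) +
                    A(i, 1) * b(t + 1, 1) * beta(t + 1, 1)) / scale[t + 1];
    }
  }
  for (int t = 0; t < n; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    gamma(t, 0) = g0 / s;
    gamma(t, 1) = g1 / s;
  }
  NumericMatrix xi(2, 2);
  for (int t = 0; t < n - 1; ++t) {
    double v[2][2];
    double denom = 0.0;
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        v[i][j] = alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j) / scale[t + 1];
        denom += v[i][j];
      }
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) xi(i, j) += v[i][j] / denom;
  }
  double ll = 0.0;
  for (int t = 0; t < n; ++t) ll += std::log(scale[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Most-probable state path (Viterbi, log space). Returns 1-based states.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, double sigma,
                          NumericMatrix A, NumericVector init) {
  const int n = x.size();
  NumericMatrix logb(n, 2);
  const double lc = -std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
  for (int t = 0; t < n; ++t)
    for (int j = 0; j < 2; ++j) {
      double z = (x[t] - mu[j]) / sigma;
      logb(t, j) = lc - 0.5 * z * z;
    }
  double logA[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      logA[i][j] = std::log(std::max(A(i, j), 1e-300));
  NumericMatrix delta(n, 2);
  IntegerMatrix psi(n, 2);
  for (int j = 0; j < 2; ++j)
    delta(0, j) = std::log(std::max(init[j], 1e-300)) + logb(0, j);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < 2; ++j) {
      double v0 = delta(t - 1, 0) + logA[0][j];
      double v1 = delta(t - 1, 1) + logA[1][j];
      if (v0 >= v1) {
        delta(t, j) = v0 + logb(t, j);
        psi(t, j) = 0;
      } else {
        delta(t, j) = v1 + logb(t, j);
        psi(t, j) = 1;
      }
    }
  }
  IntegerVector path(n);
  path[n - 1] = (delta(n - 1, 0) >= delta(n - 1, 1)) ? 0 : 1;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < n; ++t) path[t] += 1;
  return path;
}
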