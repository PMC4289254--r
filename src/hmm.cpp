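#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward pass for a 2-state Gaussian-emission HMM over one
// chromosome.  Returns the state-1 ("peak") posteriors, the log-likelihood,
// the expected transition counts and the per-state weighted moment sums
// needed for the EM M-step.
// [[Rcpp::export(name = ".fb_gauss")]]
List fb_gauss(NumericVector x, NumericVector mu, NumericVector sigma,
              NumericVector pi0, NumericMatrix A) {
  const int T = x.size();
  NumericMatrix alpha(T, 2), beta(T, 2), b(T, 2);
  NumericVector scale(T), gamma1(T);
  const double lg2pi = std::log(2.0 * M_PI);

  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < 2; ++k) {
      double z = (x[t] - mu[k]) / sigma[k];
      double ll = -0.5 * (z * z + lg2pi) - std::log(sigma[k]);
      b(t, k) = std::exp(ll);
      if (b(t, k) < 1e-300) b(t, k) = 1e-300;
    }
  }

  // forward
  double loglik = 0.0;
  alpha(0, 0) = pi0[0] * b(0, 0);
  alpha(0, 1) = pi0[1] * b(0, 1);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= scale[0]; alpha(0, 1) /= scale[0];
  loglik += std::log(scale[0]);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < 2; ++k)
      alpha(t, k) = (alpha(t - 1, 0) * A(0, k) + alpha(t - 1, 1) * A(1, k)) *
                    b(t, k);
    scale[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= scale[t]; alpha(t, 1) /= scale[t];
    loglik += std::log(scale[t]);
  }

  // backward
  beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < 2; ++k)
      beta(t, k) = (A(k, 0) * b(t + 1, 0) * beta(t + 1, 0) +
                    A(k, 1) * b(t + 1, 1) * beta(t + 1, 1)) / scale[t + 1];
  }

  // posteriors and sufficient statistics
  NumericMatrix xi(2, 2);
  NumericVector n_k(2), sx(2), sxx(2);
  double g0_first[2] = {0.0, 0.0};
  for (int t = 0; t < T; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    g0 /= s; g1 /= s;
    gamma1[t] = g1;
    n_k[0] += g0; n_k[1] += g1;
    sx[0] += g0 * x[t]; sx[1] += g1 * x[t];
    sxx[0] += g0 * x[t] * x[t]; sxx[1] += g1 * x[t] * x[t];
    if (t == 0) { g0_first[0] = g0; g0_first[1] = g1; }
    if (t < T - 1) {
      double denom = 0.0, tmp[2][2];
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < 2; ++k) {
          tmp[j][k] = alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k) /
                      scale[t + 1];
          denom += tmp[j][k];
        }
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < 2; ++k)
          xi(j, k) += tmp[j][k] / denom;
    }
  }

  return List::create(_["gamma1"] = gamma1, _["loglik"] = loglik,
                      _["xi"] = xi, _["n_k"] = n_k, _["sx"] = sx,
                      _["sxx"] = sxx,
                      _["gamma_first"] = NumericVector::create(g0_first[0],
                                                               g0_first[1]));
}
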