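#include <Rcpp.h>
using namespace Rcpp;

// Exact pre-click gain values G(t_i-) of the divisive-normalization circuit.
// Between unit-area impulses the (A, G) system is linear; propagate it in
// closed form over each inter-click interval (same math as the R reference
// gain_at_clicks()).
static void dn_kernel(double tau_R, double tau_G, double omega_I,
                      const NumericVector& times, double t_end,
                      std::vector<double>& K) {
  const double d = 1.0 / tau_R - 1.0 / tau_G;
  double A = 0.0, G = 0.0, t_prev = 0.0;
  const int n = times.size();
  K.resize(n);
  for (int i = 0; i < n; ++i) {
    const double s = times[i] - t_prev;
    if (s > 0) {
      const double h = (std::fabs(d) < 1e-12) ? s : -std::expm1(-s * d) / d;
      G = std::exp(-s / tau_G) * (G + omega_I * A * h / tau_G);
      A *= std::exp(-s / tau_R);
    }
    K[i] = std::exp(-(t_end - times[i]) / tau_R) / (tau_R * (1.0 + G));
    A += 1.0 / (tau_R * (1.0 + G));
    t_prev = times[i];
  }
}

static double bernoulli_nll(const std::vector<double>& eta,
                            const NumericVector& y, bool probit,
                            double clip) {
  double nll = 0.0;
  const int n = eta.size();
  for (int k = 0; k < n; ++k) {
    double p = probit ? R::pnorm(eta[k], 0.0, 1.0, 1, 0)
                      : 1.0 / (1.0 + std::exp(-eta[k]));
    if (p < clip) p = clip;
    if (p > 1.0 - clip) p = 1.0 - clip;
    nll -= (y[k] == 1.0) ? std::log(p) : std::log1p(-p);
  }
  return nll;
}

// [[Rcpp::export(name = ".dn_negll")]]
double dn_negll(const NumericMatrix& X, const NumericVector& y,
                const NumericVector& times, double t_end,
                double tau_R, double tau_G, double omega_I,
                double sigma, double mu, double bias, double clip) {
  std::vector<double> K;
  dn_kernel(tau_R, tau_G, omega_I, times, t_end, K);
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> eta(n, bias);
  for (int j = 0; j < m; ++j) K[j] = (K[j] + mu) / sigma;
  const double* xp = X.begin();
  for (int j = 0; j < m; ++j) {
    const double kj = K[j];
    const double* col = xp + (std::size_t)j * n;
    for (int k = 0; k < n; ++k) eta[k] += col[k] * kj;
  }
  return bernoulli_nll(eta, y, false, clip);
}

// [[Rcpp::export(name = ".lca_negll")]]
double lca_negll(const NumericMatrix& X, const NumericVector& y,
                 const NumericVector& times, double t_end,
                 double lam, double sigma_a, double bias, double clip) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> w(m);
  for (int j = 0; j < m; ++j) w[j] = std::exp(lam * (t_end - times[j]));
  const double v = (std::fabs(lam) < 1e-12)
    ? sigma_a * sigma_a * t_end
    : sigma_a * sigma_a * std::expm1(2.0 * lam * t_end) / (2.0 * lam);
  const double sd = std::sqrt(v);
  std::vector<double> eta(n, -bias);
  const double* xp = X.begin();
  for (int j = 0; j < m; ++j) {
    const double wj = w[j];
    const double* col = xp + (std::size_t)j * n;
    for (int k = 0; k < n; ++k) eta[k] += col[k] * wj;
  }
  for (int k = 0; k < n; ++k) eta[k] /= sd;
  return bernoulli_nll(eta, y, true, clip);
}
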