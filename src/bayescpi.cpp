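// Single-site Gibbs sampler for the Bayes C-pi mixture regression:
//   y = mu + sum_j x_j a_j delta_j + e,  e ~ N(0, sigma2_e I)
//   a_j | delta_j = 1 ~ N(0, sigma2_a), delta_j ~ Bern(pi),
//   pi ~ Beta(alpha, beta),
//   sigma2_a, sigma2_e ~ scaled inverse chi-squared (nu, S2).
// Uses R's RNG so chains are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bayescpi_gibbs")]]
List bayescpi_gibbs(NumericVector y, NumericMatrix X,
                    double pi_alpha, double pi_beta, double nu,
                    double S2a, double S2e,
                    int n_iter, int burn_in, int thin,
                    double pi_fixed,      // < 0 means "sample pi"
                    bool update_variances,
                    double sigma2_a_init, double sigma2_e_init) {
  const int n = y.size(), M = X.ncol();
  if (X.nrow() != n) stop("dim mismatch between y and X");
  const double *Xp = X.begin(); // column-major
  std::vector<double> xtx(M);
  for (int j = 0; j < M; ++j) {
    const double *x = Xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i] * x[i];
    xtx[j] = s;
  }
  std::vector<double> a(M, 0.0);
  std::vector<int> delta(M, 0);
  double mu = Rcpp::mean(y);
  double s2a = sigma2_a_init, s2e = sigma2_e_init;
  double pi = (pi_fixed >= 0) ? pi_fixed
                              : pi_alpha / (pi_alpha + pi_beta);
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - mu;

  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("no retained samples: check n_iter/burn_in/thin");
  IntegerVector incl_count(M);
  NumericVector a_sum(M);
  NumericVector chain_mu(n_keep), chain_pi(n_keep), chain_s2a(n_keep),
    chain_s2e(n_keep), chain_min(n_keep);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // mean
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += resid[i];
    rbar /= n;
    double mu_new = mu + rbar + norm_rand() * std::sqrt(s2e / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) resid[i] -= shift;
    mu = mu_new;

    // SNP effects and indicators
    int m_in = 0;
    double ssa = 0.0;
    const double logodds_pi = std::log(pi) - std::log1p(-pi);
    for (int j = 0; j < M; ++j) {
      const double c = xtx[j];
      if (c <= 0) { delta[j] = 0; a[j] = 0.0; continue; }
      const double *x = Xp + (size_t)j * n;
      double *r = resid.data();
      double rhs = 0.0;
      const double aold = delta[j] ? a[j] : 0.0;
      for (int i = 0; i < n; ++i) rhs += x[i] * r[i];
      rhs += c * aold;
      const double v0 = c * s2e, v1 = c * c * s2a + c * s2e;
      const double logr = 0.5 * (std::log(v0) - std::log(v1)) +
        0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1) + logodds_pi;
      const double pr = 1.0 / (1.0 + std::exp(-logr));
      const int dnew = (unif_rand() < pr) ? 1 : 0;
      double anew = 0.0;
      if (dnew) {
        const double lhs = c + s2e / s2a;
        anew = rhs / lhs + norm_rand() * std::sqrt(s2e / lhs);
        m_in += 1;
        ssa += anew * anew;
      }
      const double diff = aold - anew;
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) r[i] += x[i] * diff;
      }
      delta[j] = dnew;
      a[j] = anew;
    }

    // variances
    if (update_variances) {
      s2a = (nu * S2a + ssa) / R::rchisq(nu + m_in);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += resid[i] * resid[i];
      s2e = (nu * S2e + sse) / R::rchisq(nu + n);
      if (!R_finite(s2a) || !R_finite(s2e) || s2a <= 0 || s2e <= 0)
        stop("non-finite variance draw (iteration %d)", it + 1);
    }

    // inclusion probability
    if (pi_fixed < 0) {
      pi = R::rbeta(pi_alpha + m_in, pi_beta + M - m_in);
      pi = std::min(std::max(pi, 1e-12), 1.0 - 1e-12);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < M; ++j) {
        incl_count[j] += delta[j];
        a_sum[j] += delta[j] ? a[j] : 0.0;
      }
      chain_mu[kept] = mu;
      chain_pi[kept] = pi;
      chain_s2a[kept] = s2a;
      chain_s2e[kept] = s2e;
      chain_min[kept] = m_in;
      ++kept;
    }
  }
  return List::create(_["incl_count"] = incl_count, _["a_sum"] = a_sum,
                      _["n_kept"] = kept, _["mu"] = chain_mu,
                      _["pi"] = chain_pi, _["sigma2_a"] = chain_s2a,
                      _["sigma2_e"] = chain_s2e, _["m_in"] = chain_min);
}
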