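#include <Rcpp.h>
using namespace Rcpp;

// Additive-log-ratio random-walk Metropolis for the source-proportion
// simplex. The chain state is z in R^(K-1) with p_k = exp(z_k) / (1 + sum
// exp(z)) for k < K and p_K the remainder; the target in z-space is the
// mixing-model posterior density in p plus the ALR Jacobian sum(log p_k).
//
// Likelihood (MixSIR-style propagation): x_j ~ Normal(sum_k p_k m_kj,
// sqrt(sum_k p_k^2 s2_kj + tau2_j)). Prior: Dirichlet(alpha) on p.
//
// Proposal scales are diagonal: a global log-scale adapted by
// Robbins-Monro toward 0.30 acceptance, times the running SD of each z
// coordinate (Welford), both updated only during the first n_adapt steps
// and frozen afterwards, so burn-in and sampling use a fixed kernel.
//
// Uses R's RNG so results are reproducible under set.seed().

static double log_target(const std::vector<double>& p,
                         const NumericVector& x,
                         const NumericMatrix& m,
                         const NumericMatrix& s2,
                         const NumericVector& tau2,
                         const NumericVector& alpha) {
  const int K = m.nrow(), J = m.ncol();
  double lp = 0.0;
  for (int j = 0; j < J; ++j) {
    double mu = 0.0, v = tau2[j];
    for (int k = 0; k < K; ++k) {
      mu += p[k] * m(k, j);
      v += p[k] * p[k] * s2(k, j);
    }
    const double r = x[j] - mu;
    lp += -0.5 * std::log(2.0 * M_PI * v) - 0.5 * r * r / v;
  }
  for (int k = 0; k < K; ++k) {
    // Dirichlet kernel plus ALR Jacobian: (alpha_k - 1) log p_k + log p_k
    lp += alpha[k] * std::log(p[k]);
  }
  return lp;
}

static void alr_inverse(const std::vector<double>& z, std::vector<double>& p) {
  const int K = static_cast<int>(p.size());
  double zmax = 0.0; // implicit z_K = 0
  for (int k = 0; k < K - 1; ++k) if (z[k] > zmax) zmax = z[k];
  double denom = std::exp(-zmax);
  for (int k = 0; k < K - 1; ++k) denom += std::exp(z[k] - zmax);
  for (int k = 0; k < K - 1; ++k) p[k] = std::exp(z[k] - zmax) / denom;
  p[K - 1] = std::exp(-zmax) / denom;
}

// [[Rcpp::export]]
NumericMatrix alr_rwm_chain(NumericVector x, NumericMatrix m,
                            NumericMatrix s2, NumericVector tau2,
                            NumericVector alpha, int n_adapt, int n_burnin,
                            int n_iter, int thin, double target_accept) {
  const int K = m.nrow();
  const int d = K - 1;
  const int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, K);

  std::vector<double> z(d, 0.0), z_prop(d), p(K), p_prop(K);
  alr_inverse(z, p);
  double lp_cur = log_target(p, x, m, s2, tau2, alpha);

  // adaptation state
  double log_scale = std::log(0.5);
  std::vector<double> run_mean(d, 0.0), run_m2(d, 1.0);
  long n_seen = 1;
  std::vector<double> prop_sd(d, 0.5);

  RNGScope scope;
  const long total = static_cast<long>(n_adapt) + n_burnin +
    static_cast<long>(n_iter);
  int kept = 0;
  for (long t = 1; t <= total; ++t) {
    for (int k = 0; k < d; ++k) z_prop[k] = z[k] + norm_rand() * prop_sd[k];
    alr_inverse(z_prop, p_prop);
    const double lp_prop = log_target(p_prop, x, m, s2, tau2, alpha);
    const double log_acc = lp_prop - lp_cur;
    const bool accept = std::log(unif_rand()) < log_acc;
    if (accept) {
      z = z_prop;
      lp_cur = lp_prop;
    }
    if (t <= n_adapt) {
      // Robbins-Monro on the global scale, Welford on coordinate spread
      const double acc_prob = std::min(1.0, std::exp(log_acc));
      const double gamma = std::min(0.1, 1.0 / std::sqrt((double)t));
      log_scale += gamma * (acc_prob - target_accept);
      ++n_seen;
      for (int k = 0; k < d; ++k) {
        const double delta = z[k] - run_mean[k];
        run_mean[k] += delta / n_seen;
        run_m2[k] += delta * (z[k] - run_mean[k]);
        const double sd_k = std::sqrt(run_m2[k] / (n_seen - 1) + 1e-3);
        prop_sd[k] = std::exp(log_scale) * sd_k;
      }
    }
    const long t_sample = t - n_adapt - n_burnin;
    if (t_sample >= 1 && t_sample % thin == 0 && kept < n_keep) {
      alr_inverse(z, p);
      for (int k = 0; k < K; ++k) draws(kept, k) = p[k];
      ++kept;
    }
  }
  return draws;
}
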