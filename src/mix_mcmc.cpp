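#include <Rcpp.h>
using namespace Rcpp;

// Log of the unnormalized posterior over diet proportions p, evaluated for
// one consumer (or a pooled set of observations sharing p).
//
//   m_j  = sum_k w_jk * a_jk          a_jk = source mean + TDF mean
//   s2_j = sum_k w_jk^2 * v_jk        v_jk = source var  + TDF var
//   w_jk = p_k                        (equal elemental concentrations)
//        = p_k q_jk / sum_k p_k q_jk  (concentration-dependent)
//
// plus the Dirichlet(alpha) prior and the log-ratio Jacobian sum(log p_k)
// (the sampler walks in ilr coordinates).
static double log_target(const NumericVector& p,
                         const NumericMatrix& x,   // n_obs x J
                         const NumericMatrix& a,   // J x K
                         const NumericMatrix& v,   // J x K
                         const NumericMatrix& q,   // J x K concentrations
                         const NumericVector& alpha,
                         const bool conc_dep) {
  const int n = x.nrow(), J = x.ncol(), K = p.size();
  double lp = 0.0;
  for (int j = 0; j < J; ++j) {
    double m = 0.0, s2 = 0.0;
    if (conc_dep) {
      double wsum = 0.0;
      for (int k = 0; k < K; ++k) wsum += p[k] * q(j, k);
      for (int k = 0; k < K; ++k) {
        const double w = p[k] * q(j, k) / wsum;
        m  += w * a(j, k);
        s2 += w * w * v(j, k);
      }
    } else {
      for (int k = 0; k < K; ++k) {
        m  += p[k] * a(j, k);
        s2 += p[k] * p[k] * v(j, k);
      }
    }
    if (s2 <= 0.0) return R_NegInf;
    const double c = -0.5 * std::log(2.0 * M_PI * s2);
    for (int i = 0; i < n; ++i) {
      const double r = x(i, j) - m;
      lp += c - r * r / (2.0 * s2);
    }
  }
  for (int k = 0; k < K; ++k) {
    // prior (alpha_k - 1) log p_k plus Jacobian log p_k
    lp += alpha[k] * std::log(p[k]);
  }
  return lp;
}

// p = closure(exp(V z)): inverse ilr with orthonormal basis V (K x (K-1))
static void ilr_inv(const NumericVector& z, const NumericMatrix& V,
                    NumericVector& p) {
  const int K = V.nrow(), D = V.ncol();
  double mx = R_NegInf;
  for (int k = 0; k < K; ++k) {
    double u = 0.0;
    for (int d = 0; d < D; ++d) u += V(k, d) * z[d];
    p[k] = u;
    if (u > mx) mx = u;
  }
  double s = 0.0;
  for (int k = 0; k < K; ++k) { p[k] = std::exp(p[k] - mx); s += p[k]; }
  for (int k = 0; k < K; ++k) p[k] /= s;
}

// Adaptive random-walk Metropolis in ilr coordinates. Proposal scale is
// tuned by Robbins-Monro during burn-in toward a 0.30 acceptance rate and
// frozen afterwards. Uses R's RNG, so draws are reproducible under
// set.seed() on the R side.
// [[Rcpp::export]]
List mix_mcmc_cpp(const NumericMatrix x, const NumericMatrix a,
                  const NumericMatrix v, const NumericMatrix q,
                  const NumericVector alpha, const NumericMatrix V,
                  const int n_iter, const int n_burn, const int thin,
                  const bool conc_dep, const double init_sd) {
  const int K = V.nrow(), D = V.ncol();
  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix draws(n_keep, K);

  NumericVector z(D), z_prop(D), p(K), p_prop(K);
  for (int d = 0; d < D; ++d) z[d] = R::norm_rand() * init_sd;
  ilr_inv(z, V, p);
  double lt = log_target(p, x, a, v, q, alpha, conc_dep);

  double lscale = std::log(2.38 / std::sqrt((double) D));
  int kept = 0;
  long acc_post = 0, n_post = 0;
  for (int t = 0; t < n_iter; ++t) {
    const double scale = std::exp(lscale);
    for (int d = 0; d < D; ++d) z_prop[d] = z[d] + scale * R::norm_rand();
    ilr_inv(z_prop, V, p_prop);
    const double lt_prop = log_target(p_prop, x, a, v, q, alpha, conc_dep);
    const double lr = lt_prop - lt;
    const double apr = (lr >= 0.0) ? 1.0 : std::exp(lr);
    bool accepted = false;
    if (unif_rand() < apr) {
      for (int d = 0; d < D; ++d) z[d] = z_prop[d];
      for (int k = 0; k < K; ++k) p[k] = p_prop[k];
      lt = lt_prop;
      accepted = true;
    }
    if (t < n_burn) {
      lscale += (apr - 0.30) / std::sqrt((double) (t + 1));
    } else {
      if (accepted) acc_post++;
      n_post++;
      if ((t - n_burn) % thin == 0) {
        for (int k = 0; k < K; ++k) draws(kept, k) = p[k];
        kept++;
      }
    }
  }
  const double acc_rate = n_post > 0 ? (double) acc_post / (double) n_post : NA_REAL;
  return List::create(_["draws"] = draws,
                      _["acceptance_rate"] = acc_rate,
                      _["scale"] = std::exp(lscale));
}
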