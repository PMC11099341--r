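// Single-chain Gibbs sampler for the spike-plus-Gaussian-mixture regression
// y = X b + e with per-feature prior  b_j ~ pi_0 d_0 + sum_k pi_k N(0, v_k),
// v_k fixed fractions of the (unit) phenotypic variance. Supports one or two
// feature classes (e.g. methylation and genotype), each with its own mixture
// proportions and variances. Uses R's RNG so chains are seeded from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static int sample_discrete(const arma::vec &logw) {
  arma::vec w = arma::exp(logw - logw.max());
  w /= arma::accu(w);
  double u = R::unif_rand(), acc = 0.0;
  for (arma::uword k = 0; k < w.n_elem; ++k) {
    acc += w(k);
    if (u <= acc) return (int)k;
  }
  return (int)w.n_elem - 1;
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(const arma::mat &X, const arma::vec &y,
                 const arma::ivec &class_id, const List &mix_var_list,
                 int n_iter, int burn_in, int thin,
                 double fix_sigma2e, const arma::vec &fix_pi,
                 double dirichlet_alpha, double nu0, double s0) {
  const int n = X.n_rows, m = X.n_cols;
  const int n_class = mix_var_list.size();

  const bool pi_fixed = fix_pi.n_elem > 0;
  std::vector<arma::vec> mixvar(n_class);
  std::vector<arma::vec> pi(n_class);
  for (int c = 0; c < n_class; ++c) {
    mixvar[c] = as<arma::vec>(mix_var_list[c]);
    if (pi_fixed) {
      pi[c] = fix_pi;
    } else {
      // sparse initialization: the spike starts with 95% mass so null
      // features are not swept in during early iterations
      const int K = mixvar[c].n_elem;
      pi[c] = arma::vec(K + 1, arma::fill::value(0.05 / K));
      pi[c](0) = 0.95;
    }
  }

  arma::vec xtx(m);
  for (int j = 0; j < m; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  arma::vec beta(m, arma::fill::zeros);
  arma::ivec comp(m, arma::fill::zeros);
  arma::vec resid = y;
  double s2e = (fix_sigma2e > 0) ? fix_sigma2e : 1.0;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_draws(m, n_keep);
  arma::imat comp_draws(m, n_keep);
  arma::vec s2e_draws(n_keep);
  List pi_draws(n_class);
  std::vector<arma::mat> pi_store(n_class);
  for (int c = 0; c < n_class; ++c)
    pi_store[c] = arma::mat(mixvar[c].n_elem + 1, n_keep);

  arma::uvec order = arma::regspace<arma::uvec>(0, m - 1);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // randomized feature update order mitigates order artifacts in blocks
    for (int j = m - 1; j > 0; --j) {
      int jj = (int)std::floor(R::unif_rand() * (j + 1));
      std::swap(order(j), order(jj));
    }
    for (int idx = 0; idx < m; ++idx) {
      const int j = order(idx);
      const int c = class_id(j);
      const arma::vec &vk = mixvar[c];
      const int K = vk.n_elem;
      double rhs = arma::dot(X.col(j), resid) + beta(j) * xtx(j);
      arma::vec logw(K + 1);
      logw(0) = pi[c](0) > 0 ? std::log(pi[c](0)) : -1e300;
      for (int k = 0; k < K; ++k) {
        double denom = xtx(j) + s2e / vk(k);
        logw(k + 1) = (pi[c](k + 1) > 0 ? std::log(pi[c](k + 1)) : -1e300)
          - 0.5 * std::log(vk(k) * xtx(j) / s2e + 1.0)
          + 0.5 * rhs * rhs / (s2e * denom);
      }
      int k_new = sample_discrete(logw);
      double b_new = 0.0;
      if (k_new > 0) {
        double denom = xtx(j) + s2e / vk(k_new - 1);
        double mu = rhs / denom;
        double sd = std::sqrt(s2e / denom);
        b_new = mu + sd * R::norm_rand();
      }
      if (b_new != beta(j)) {
        resid += X.col(j) * (beta(j) - b_new);
        beta(j) = b_new;
      }
      comp(j) = k_new;
    }
    // mixture proportions: Dirichlet(alpha + counts) per class; alpha < 1
    // encourages sparsity when the feature count is modest
    if (!pi_fixed) {
      for (int c = 0; c < n_class; ++c) {
        const int K = mixvar[c].n_elem;
        arma::vec cnt(K + 1, arma::fill::value(dirichlet_alpha));
        for (int j = 0; j < m; ++j)
          if (class_id(j) == c) cnt(comp(j)) += 1.0;
        arma::vec gam(K + 1);
        for (int k = 0; k <= K; ++k) gam(k) = R::rgamma(cnt(k), 1.0);
        pi[c] = gam / arma::accu(gam);
      }
    }
    // residual variance: scaled-inverse-chi-square
    if (fix_sigma2e <= 0) {
      double rss = arma::dot(resid, resid);
      s2e = (rss + nu0 * s0) / R::rchisq((double)n + nu0);
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      beta_draws.col(kept) = beta;
      comp_draws.col(kept) = comp;
      s2e_draws(kept) = s2e;
      for (int c = 0; c < n_class; ++c) pi_store[c].col(kept) = pi[c];
      ++kept;
    }
  }
  for (int c = 0; c < n_class; ++c) pi_draws[c] = pi_store[c];
  return List::create(_["beta"] = beta_draws, _["comp"] = comp_draws,
                      _["sigma2e"] = s2e_draws, _["pi"] = pi_draws,
                      _["n_keep"] = kept);
}
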