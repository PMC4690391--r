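// Stochastic search variable selection Gibbs sampler.
//
// Model: y = intercept(group) + sum_j X_j beta_j + e,  e ~ N(0, I s2e).
// Mixture prior per marker: beta_j ~ N(0, s2b) when gamma_j = 1 (prior
// probability pi_large) and N(0, s2b / ratio) when gamma_j = 0. The indicator
// is sampled from its Bernoulli full conditional via the marginal densities of
// the marker's right-hand side under each component (log-space); beta_j from
// its normal full conditional with incremental residual updating; s2b from a
// scaled inverse chi-square (both components share s2b up to the fixed
// ratio); s2e from e'e / chisq(n).
//
// Uses R's RNG so set.seed() in R controls the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List ssvs_gibbs_cpp(const arma::mat& X,        // centered reference markers n x m
                    const arma::vec& y,
                    const arma::uvec& group,   // 0-based intercept group per individual
                    const int n_groups,
                    const arma::mat& Xc,       // centered candidate markers, same columns
                    const int n_iter,
                    const int burn_in,
                    const double pi_large,
                    const double ratio,
                    const double df0,
                    const double S0,
                    const bool random_order,
                    const int debug_every,
                    const double fix_s2b,   // > 0: hold sigma2_beta fixed
                    const double fix_s2e) { // > 0: hold sigma2_e fixed
  const int n = X.n_rows, m = X.n_cols, nc = Xc.n_rows;
  if ((int) y.n_elem != n) stop("phenotype length mismatch");

  arma::vec xtx(m);
  for (int j = 0; j < m; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));

  // group bookkeeping
  arma::vec ng(n_groups, arma::fill::zeros);
  for (int i = 0; i < n; ++i) ng[group[i]] += 1.0;

  // initial state
  arma::vec mu(n_groups, arma::fill::zeros);
  for (int i = 0; i < n; ++i) mu[group[i]] += y[i];
  mu /= ng;
  arma::vec beta(m, arma::fill::zeros);
  arma::ivec gamma(m, arma::fill::zeros);
  arma::vec e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu[group[i]];
  double s2e = arma::dot(e, e) / std::max(1, n - 1) * 0.5;
  if (s2e <= 0) s2e = 1e-8;
  double s2b = S0;
  if (fix_s2b > 0) s2b = fix_s2b;
  if (fix_s2e > 0) s2e = fix_s2e;

  // accumulators
  arma::vec beta_sum(m, arma::fill::zeros), incl_sum(m, arma::fill::zeros);
  arma::vec mu_sum(n_groups, arma::fill::zeros);
  arma::vec gebv_sum(nc, arma::fill::zeros);
  double s2b_sum = 0.0, s2e_sum = 0.0;
  double max_resid_drift = 0.0;
  int n_keep = 0;

  const double log_p1 = std::log(pi_large), log_p0 = std::log1p(-pi_large);
  arma::uvec order = arma::regspace<arma::uvec>(0, m - 1);

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // intercepts, flat prior
    for (int g = 0; g < n_groups; ++g) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) if ((int) group[i] == g) rhs += e[i] + mu[g];
      double mu_new = R::rnorm(rhs / ng[g], std::sqrt(s2e / ng[g]));
      double d = mu[g] - mu_new;
      for (int i = 0; i < n; ++i) if ((int) group[i] == g) e[i] += d;
      mu[g] = mu_new;
    }

    if (random_order) {
      // Fisher-Yates with R's RNG
      for (int j = m - 1; j > 0; --j) {
        int k = (int) std::floor(unif_rand() * (j + 1));
        std::swap(order[j], order[k]);
      }
    }

    double ss_beta = 0.0;
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      if (xtx[j] <= 0) { beta[j] = 0.0; gamma[j] = 0; continue; }
      const double r = arma::dot(X.col(j), e) + xtx[j] * beta[j];
      const double v1 = xtx[j] * s2e + xtx[j] * xtx[j] * s2b;
      const double v0 = xtx[j] * s2e + xtx[j] * xtx[j] * s2b / ratio;
      // log marginal densities of the right-hand side under each component
      const double l1 = -0.5 * std::log(v1) - 0.5 * r * r / v1 + log_p1;
      const double l0 = -0.5 * std::log(v0) - 0.5 * r * r / v0 + log_p0;
      const double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
      const int g_new = (unif_rand() < p1) ? 1 : 0;
      const double v = g_new ? s2b : s2b / ratio;
      const double C = xtx[j] + s2e / v;
      const double b_new = R::rnorm(r / C, std::sqrt(s2e / C));
      const double d = beta[j] - b_new;
      if (d != 0.0) e += X.col(j) * d;
      beta[j] = b_new;
      gamma[j] = g_new;
      ss_beta += b_new * b_new * (g_new ? 1.0 : ratio);
    }

    // shared prior variance of the mixture, scaled inverse chi-square
    if (fix_s2b <= 0) {
      const double df_b = df0 + m;
      s2b = (df0 * S0 + ss_beta) / R::rchisq(df_b);
    }
    // residual variance
    if (fix_s2e <= 0) s2e = arma::dot(e, e) / R::rchisq((double) n);
    if (!std::isfinite(s2e) || !std::isfinite(s2b)) {
      stop("chain diverged (non-finite variance) at iteration %d", it);
    }

    if (debug_every > 0 && it % debug_every == 0) {
      arma::vec e_full = y - X * beta;
      for (int i = 0; i < n; ++i) e_full[i] -= mu[group[i]];
      const double drift = arma::abs(e_full - e).max();
      if (drift > max_resid_drift) max_resid_drift = drift;
    }

    if (it > burn_in) {
      ++n_keep;
      beta_sum += beta;
      for (int j = 0; j < m; ++j) incl_sum[j] += gamma[j];
      mu_sum += mu;
      s2b_sum += s2b;
      s2e_sum += s2e;
      if (nc > 0) gebv_sum += Xc * beta;
    }
  }

  return List::create(
    _["beta_mean"] = beta_sum / n_keep,
    _["inclusion_prob"] = incl_sum / n_keep,
    _["mu_mean"] = mu_sum / n_keep,
    _["sigma2_beta_mean"] = s2b_sum / n_keep,
    _["sigma2_e_mean"] = s2e_sum / n_keep,
    _["gebv"] = gebv_sum / std::max(1, n_keep),
    _["n_kept"] = n_keep,
    _["max_resid_drift"] = max_resid_drift);
}
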