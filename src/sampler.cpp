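// Metropolis-within-Gibbs core for the constrained Bayesian logistic model.
// Blockwise random-walk proposals; proposals violating any inequality have
// zero prior density and are rejected outright; shared block variances are
// refreshed by conjugate inverse-gamma draws (exact under the truncation
// because the constrained priors are mean-zero and the feasible region is a
// cone, whose normal measure is scale invariant). Uses R's RNG throughout so
// results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double bern_loglik(const arma::vec& eta, const arma::vec& y) {
  const arma::uword n = eta.n_elem;
  double ll = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double e = eta[i];
    const double m = e > 0.0 ? e : 0.0;
    ll += y[i] * e - (m + std::log1p(std::exp(-std::fabs(e))));
  }
  return ll;
}

// [[Rcpp::export]]
List mcmc_chain_cpp(const arma::mat& X, const arma::vec& y,
                    const List& block_cols,
                    const arma::vec& beta_init,
                    const arma::vec& prior_mean,
                    const arma::vec& prior_sd,
                    const IntegerVector& var_group,
                    const int n_groups,
                    const double ig_shape, const double ig_scale,
                    const IntegerMatrix& cons_idx,
                    const NumericMatrix& cons_sign,
                    const List& cons_by_block,
                    const int iterations, const int burn_in,
                    const NumericVector& prop_scale_in, const bool adapt) {
  const int p = X.n_cols;
  const int B = block_cols.size();
  NumericVector prop_scale = clone(prop_scale_in);

  arma::vec beta = beta_init;
  arma::vec eta = X * beta;
  double cur_ll = bern_loglik(eta, y);

  arma::vec sigma2(std::max(n_groups, 1));
  sigma2.fill(ig_scale / (ig_shape - 1.0));
  std::vector< std::vector<int> > gmem(std::max(n_groups, 1));
  for (int j = 0; j < p; ++j) {
    const int g = var_group[j];
    if (g > 0) gmem[g - 1].push_back(j);
  }

  arma::mat draws(iterations, p);
  arma::mat sig_draws(iterations, std::max(n_groups, 1));
  std::vector<double> acc(B, 0.0), acc_win(B, 0.0);
  const int win = 50;
  const int total = burn_in + iterations;

  for (int it = 0; it < total; ++it) {
    for (int b = 0; b < B; ++b) {
      IntegerVector cols = block_cols[b];
      const int k = cols.size();
      if (k == 0) continue;
      arma::vec newbeta = beta;
      for (int u = 0; u < k; ++u) {
        const int j = cols[u] - 1;
        newbeta[j] = beta[j] + prop_scale[b] * norm_rand();
      }
      bool ok = true;
      IntegerVector crows = cons_by_block[b];
      for (int u = 0; u < crows.size(); ++u) {
        const int r = crows[u] - 1;
        const int i1 = cons_idx(r, 0), i2 = cons_idx(r, 1);
        double v = cons_sign(r, 0) * newbeta[i1 - 1];
        if (i2 > 0) v += cons_sign(r, 1) * newbeta[i2 - 1];
        if (v < 0.0) { ok = false; break; }
      }
      if (ok) {
        arma::uvec csub(k);
        arma::vec dsub(k);
        for (int u = 0; u < k; ++u) {
          const int j = cols[u] - 1;
          csub[u] = j;
          dsub[u] = newbeta[j] - beta[j];
        }
        arma::vec eta_new = eta + X.cols(csub) * dsub;
        const double ll_new = bern_loglik(eta_new, y);
        double lpr = 0.0;
        for (int u = 0; u < k; ++u) {
          const int j = cols[u] - 1;
          const int g = var_group[j];
          const double sd = (g > 0) ? std::sqrt(sigma2[g - 1]) : prior_sd[j];
          const double d1 = newbeta[j] - prior_mean[j];
          const double d0 = beta[j] - prior_mean[j];
          lpr += (d0 * d0 - d1 * d1) / (2.0 * sd * sd);
        }
        const double la = ll_new - cur_ll + lpr;
        if (la >= 0.0 || std::log(unif_rand()) < la) {
          beta = newbeta;
          eta = eta_new;
          cur_ll = ll_new;
          if (it >= burn_in) acc[b] += 1.0;
          acc_win[b] += 1.0;
        }
      }
      if (adapt && it < burn_in && ((it + 1) % win) == 0) {
        const double rate = acc_win[b] / win;
        prop_scale[b] *= std::exp(1.5 * (rate - 0.3));
        if (prop_scale[b] < 1e-5) prop_scale[b] = 1e-5;
        if (prop_scale[b] > 10.0) prop_scale[b] = 10.0;
        acc_win[b] = 0.0;
      }
    }
    for (int g = 0; g < n_groups; ++g) {
      const std::vector<int>& mem = gmem[g];
      const int k = mem.size();
      if (k <= 1) {
        // degenerate group: draw from the prior
        sigma2[g] = 1.0 / R::rgamma(ig_shape, 1.0 / ig_scale);
      } else {
        double ss = 0.0;
        for (size_t u = 0; u < mem.size(); ++u) {
          const double d = beta[mem[u]] - prior_mean[mem[u]];
          ss += d * d;
        }
        sigma2[g] = 1.0 / R::rgamma(ig_shape + 0.5 * k,
                                    1.0 / (ig_scale + 0.5 * ss));
      }
    }
    if (it >= burn_in) {
      draws.row(it - burn_in) = beta.t();
      sig_draws.row(it - burn_in) = sigma2.t();
    }
  }
  NumericVector acc_rate(B);
  for (int b = 0; b < B; ++b) acc_rate[b] = acc[b] / iterations;
  return List::create(_["draws"] = draws, _["sigma2"] = sig_draws,
                      _["accept"] = acc_rate,
                      _["prop_scale"] = prop_scale);
}
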