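// Metropolis-within-Gibbs sampler for a Bayesian cumulative-logit
// (proportional-odds) model with optional dam random intercept.
// Severity orientation: logit P(Y <= j) = alpha_j - eta, eta = x'beta + d,
// so positive coefficients increase marking severity.
// Random-walk updates with per-parameter step adaptation during burn-in
// only; all randomness from R's RNG.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double plogis_(double x) { return ::Rf_plogis(x, 0.0, 1.0, 1, 0); }

// log P(Y = y | eta) for cutpoints c (ascending, length K-1)
static inline double ll_rec(int y, double eta, const std::vector<double>& c) {
  const int K1 = c.size();
  double hi = (y == K1) ? 1.0 : plogis_(c[y] - eta);
  double lo = (y == 0) ? 0.0 : plogis_(c[y - 1] - eta);
  double pr = hi - lo;
  return (pr > 0.0) ? std::log(pr) : -1e300;
}

// [[Rcpp::export]]
List cumlogit_mcmc_cpp(IntegerVector y, NumericMatrix X, IntegerVector dam,
                       int n_dam, int K,
                       double prior_sd_beta, double prior_sd_alpha,
                       double prior_sd_tau,
                       NumericVector alpha_start, double tau_start,
                       int niter, int burnin, int thin) {
  const int n = y.size(), p = X.ncol(), K1 = K - 1;
  const bool use_dam = n_dam > 0;

  std::vector<double> alpha(alpha_start.begin(), alpha_start.end());
  std::vector<double> beta(p, 0.0), d(n_dam, 0.0);
  double tau = tau_start;
  std::vector<double> eta(n, 0.0);

  // record lists per response class (for cutpoint updates) and per dam
  std::vector<std::vector<int>> class_recs(K), dam_recs(n_dam);
  for (int r = 0; r < n; ++r) {
    class_recs[y[r]].push_back(r);
    if (use_dam && dam[r] >= 0) dam_recs[dam[r]].push_back(r);
  }

  std::vector<double> step_b(p, 0.1), step_a(K1, 0.1), step_d(n_dam, 0.5);
  double step_t = 0.3;
  std::vector<int> acc_b(p, 0), acc_a(K1, 0), acc_d(n_dam, 0);
  int acc_t = 0, adapt_win = 50;

  const int n_store = (niter - burnin) / thin;
  NumericMatrix a_draws(n_store, K1), b_draws(n_store, p);
  NumericVector tau_draws(n_store);
  NumericMatrix d_mean(1, n_dam);
  int stored = 0;
  long long acc_b_tot = 0, try_b_tot = 0;

  auto ll_all = [&](const std::vector<double>& c) {
    double s = 0.0;
    for (int r = 0; r < n; ++r) s += ll_rec(y[r], eta[r], c);
    return s;
  };
  double cur_ll = ll_all(alpha);

  for (int iter = 0; iter < niter; ++iter) {
    if ((iter & 255) == 0) Rcpp::checkUserInterrupt();

    // -- beta: random-walk, full-data likelihood -------------------------
    for (int j = 0; j < p; ++j) {
      double delta = step_b[j] * ::norm_rand();
      double newll = 0.0;
      for (int r = 0; r < n; ++r)
        newll += ll_rec(y[r], eta[r] + X(r, j) * delta, alpha);
      double bj = beta[j], bn = bj + delta;
      double lpr = -0.5 * (bn * bn - bj * bj) / (prior_sd_beta * prior_sd_beta);
      ++try_b_tot;
      if (std::log(::unif_rand()) < newll - cur_ll + lpr) {
        for (int r = 0; r < n; ++r) eta[r] += X(r, j) * delta;
        beta[j] = bn;
        cur_ll = newll;
        ++acc_b[j]; ++acc_b_tot;
      }
    }

    // -- alpha: random-walk with ordering rejection ----------------------
    for (int j = 0; j < K1; ++j) {
      double an = alpha[j] + step_a[j] * ::norm_rand();
      double lo = (j == 0) ? R_NegInf : alpha[j - 1];
      double hi = (j == K1 - 1) ? R_PosInf : alpha[j + 1];
      if (an <= lo || an >= hi) continue;
      // only classes j and j+1 involve cutpoint j
      double dll = 0.0;
      std::vector<double> anew = alpha; anew[j] = an;
      for (int cls : {j, j + 1})
        for (int r : class_recs[cls])
          dll += ll_rec(y[r], eta[r], anew) - ll_rec(y[r], eta[r], alpha);
      double lpr = -0.5 * (an * an - alpha[j] * alpha[j]) /
                   (prior_sd_alpha * prior_sd_alpha);
      if (std::log(::unif_rand()) < dll + lpr) {
        alpha[j] = an;
        cur_ll += dll;
        ++acc_a[j];
      }
    }

    // -- dam effects -------------------------------------------------------
    if (use_dam) {
      for (int i = 0; i < n_dam; ++i) {
        double delta = step_d[i] * ::norm_rand();
        double dn = d[i] + delta, dll = 0.0;
        for (int r : dam_recs[i])
          dll += ll_rec(y[r], eta[r] + delta, alpha) - ll_rec(y[r], eta[r], alpha);
        double lpr = -0.5 * (dn * dn - d[i] * d[i]) / (tau * tau);
        if (std::log(::unif_rand()) < dll + lpr) {
          for (int r : dam_recs[i]) eta[r] += delta;
          d[i] = dn;
          cur_ll += dll;
          ++acc_d[i];
        }
      }
      // -- tau: random-walk on log scale, half-normal prior ---------------
      {
        double lt = std::log(tau), ltn = lt + step_t * ::norm_rand();
        double tn = std::exp(ltn);
        double sumsq = 0.0;
        for (int i = 0; i < n_dam; ++i) sumsq += d[i] * d[i];
        auto lp = [&](double tv, double ltv) {
          return -n_dam * ltv - 0.5 * sumsq / (tv * tv)
                 - 0.5 * tv * tv / (prior_sd_tau * prior_sd_tau) + ltv; // + Jacobian
        };
        if (std::log(::unif_rand()) < lp(tn, ltn) - lp(tau, lt)) { tau = tn; ++acc_t; }
      }
    }

    // -- step adaptation (burn-in only) ----------------------------------
    if (iter < burnin && (iter + 1) % adapt_win == 0) {
      auto tune = [&](double& s, int& a) {
        double rate = (double)a / adapt_win;
        s *= std::exp(0.6 * (rate - 0.44));
        s = std::min(std::max(s, 1e-4), 50.0);
        a = 0;
      };
      for (int j = 0; j < p; ++j) tune(step_b[j], acc_b[j]);
      for (int j = 0; j < K1; ++j) tune(step_a[j], acc_a[j]);
      if (use_dam) {
        for (int i = 0; i < n_dam; ++i) tune(step_d[i], acc_d[i]);
        tune(step_t, acc_t);
      }
    }

    if (iter >= burnin && (iter - burnin) % thin == 0 && stored < n_store) {
      for (int j = 0; j < K1; ++j) a_draws(stored, j) = alpha[j];
      for (int j = 0; j < p; ++j) b_draws(stored, j) = beta[j];
      tau_draws[stored] = use_dam ? tau : NA_REAL;
      for (int i = 0; i < n_dam; ++i) d_mean(0, i) += d[i];
      ++stored;
    }
  }
  if (stored > 0) for (int i = 0; i < n_dam; ++i) d_mean(0, i) /= stored;

  return List::create(
    _["alpha"] = a_draws, _["beta"] = b_draws, _["tau"] = tau_draws,
    _["dam_mean"] = d_mean, _["n_stored"] = stored,
    _["accept_beta"] = try_b_tot > 0 ? (double)acc_b_tot / try_b_tot : NA_REAL);
}
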