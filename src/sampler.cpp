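#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(1 - exp(eta)) for eta < 0, numerically stable on both sides of -log 2
static inline double l1me(double eta) {
  return eta < -0.6931471805599453 ? log1p(-exp(eta)) : log(-expm1(eta));
}

// Bernoulli log-likelihood with log link; for y = 1 it is just eta
static inline double bern_ll(double y, double eta) {
  return y == 1.0 ? eta : l1me(eta);
}

// lower Cholesky of a small symmetric positive-definite matrix
static bool cholesky(const std::vector<double>& A, int p, std::vector<double>& L) {
  L.assign(p * p, 0.0);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * p + j];
      for (int k = 0; k < j; ++k) s -= L[i * p + k] * L[j * p + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * p + i] = std::sqrt(s);
      } else {
        L[i * p + j] = s / L[j * p + j];
      }
    }
  }
  return true;
}

// Adaptive Metropolis-within-Gibbs for the Bayesian log-binomial GLMM:
// Bernoulli outcome with log link, fixed effects X, person and cluster
// normal random intercepts, N(0, beta_sd^2) priors on fixed effects and
// half-normal(re_scale) priors on the random-effect SDs. Proposals that
// would put any fitted probability at or above 1 are rejected (truncated
// support). Moves per sweep: single-site random walks on each fixed
// effect and random intercept; repeated joint fixed-effect updates with
// proposal covariance adapted from the chain's own burn-in history;
// log-scale random walks on the random-effect SDs; and joint group-scale
// moves rescaling each random-effect vector together with its SD (this
// removes the funnel coupling between a variance component and its
// effects). All adaptation happens during burn-in only. Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export(name = ".mwg_sampler")]]
List mwg_sampler(const NumericVector& y, const NumericMatrix& X,
                 const IntegerVector& person, const IntegerVector& cluster,
                 double beta_sd, double re_scale_p, double re_scale_c,
                 int n_iter, int burnin, int thin,
                 const NumericVector& beta_init,
                 double sigma_p_init, double sigma_c_init) {
  const int n = y.size(), p = X.ncol();
  int np = 0, nc = 0;
  for (int i = 0; i < n; ++i) {
    if (person[i] + 1 > np) np = person[i] + 1;
    if (cluster[i] + 1 > nc) nc = cluster[i] + 1;
  }

  std::vector< std::vector<int> > colrows(p), prows(np), crows(nc);
  std::vector< std::vector<double> > colvals(p);
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i)
      if (X(i, k) != 0.0) { colrows[k].push_back(i); colvals[k].push_back(X(i, k)); }
  for (int i = 0; i < n; ++i) {
    prows[person[i]].push_back(i);
    crows[cluster[i]].push_back(i);
  }

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> u(np, 0.0), v(nc, 0.0), eta(n), ll(n);
  double sigma_p = sigma_p_init, sigma_c = sigma_c_init;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int k = 0; k < p; ++k) e += X(i, k) * beta[k];
    eta[i] = e + u[person[i]] + v[cluster[i]];
    if (eta[i] >= 0.0) stop("initial linear predictor not in support (eta >= 0)");
    ll[i] = bern_ll(y[i], eta[i]);
  }

  std::vector<double> ls_beta(p, std::log(0.05)), ls_u(np, std::log(0.5)),
      ls_v(nc, std::log(0.5));
  double ls_sp = std::log(0.3), ls_sc = std::log(0.3);
  double ls_scale_p = std::log(0.1), ls_scale_c = std::log(0.1);
  double ls_joint = 0.0;
  const double target = 0.44, target_joint = 0.234;

  std::vector<double> cov_mean(p, 0.0), cov_M2(p * p, 0.0), chol_L;
  long n_cov = 0;
  bool have_chol = false;
  const int cov_start = burnin / 5, joint_start = burnin / 2;
  std::vector<double> dbeta(p), znorm(p), eta_prop(n), ll_prop(n), scratch(64);

  const int n_store = (n_iter - burnin + thin - 1) / thin;
  NumericMatrix beta_draws(n_store, p), u_draws(n_store, np), v_draws(n_store, nc);
  NumericVector sp_draws(n_store), sc_draws(n_store);
  int stored = 0;

  RNGScope scope;
  for (int t = 0; t < n_iter; ++t) {
    const double gamma = (t < burnin) ? std::pow(t + 1.0, -0.6) : 0.0;

    // fixed effects, one at a time (cheap, keeps conditionals moving)
    for (int k = 0; k < p; ++k) {
      const double delta = norm_rand() * std::exp(ls_beta[k]);
      const std::vector<int>& rows = colrows[k];
      const std::vector<double>& vals = colvals[k];
      if (scratch.size() < rows.size()) scratch.resize(rows.size());
      double dlp = 0.0;
      bool ok = true;
      for (size_t r = 0; r < rows.size(); ++r) {
        const int i = rows[r];
        const double ne = eta[i] + vals[r] * delta;
        if (ne >= 0.0) { ok = false; break; }
        const double lp = bern_ll(y[i], ne);
        scratch[r] = lp;
        dlp += lp - ll[i];
      }
      double a = 0.0;
      if (ok) {
        const double b0 = beta[k], b1 = beta[k] + delta;
        dlp += (b0 * b0 - b1 * b1) / (2.0 * beta_sd * beta_sd);
        a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < a) {
          beta[k] += delta;
          for (size_t r = 0; r < rows.size(); ++r) {
            const int i = rows[r];
            eta[i] += vals[r] * delta;
            ll[i] = scratch[r];
          }
        }
      }
      if (gamma > 0.0) ls_beta[k] += gamma * (a - target);
    }

    // joint fixed-effect moves with adapted covariance (repeated: the
    // correlated fixed effects are the slow directions of the posterior)
    if (t >= joint_start && have_chol) for (int rep = 0; rep < 3; ++rep) {
      for (int k = 0; k < p; ++k) znorm[k] = norm_rand();
      const double sc = std::exp(ls_joint) * 2.38 / std::sqrt((double) p);
      for (int k = 0; k < p; ++k) {
        double s = 0.0;
        for (int j = 0; j <= k; ++j) s += chol_L[k * p + j] * znorm[j];
        dbeta[k] = sc * s;
      }
      bool ok = true;
      double dlp = 0.0;
      for (int i = 0; i < n; ++i) {
        double de = 0.0;
        for (int k = 0; k < p; ++k) de += X(i, k) * dbeta[k];
        const double ne = eta[i] + de;
        if (ne >= 0.0) { ok = false; break; }
        eta_prop[i] = ne;
        const double lp = bern_ll(y[i], ne);
        ll_prop[i] = lp;
        dlp += lp - ll[i];
      }
      double a = 0.0;
      if (ok) {
        for (int k = 0; k < p; ++k) {
          const double b0 = beta[k], b1 = beta[k] + dbeta[k];
          dlp += (b0 * b0 - b1 * b1) / (2.0 * beta_sd * beta_sd);
        }
        a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < a) {
          for (int k = 0; k < p; ++k) beta[k] += dbeta[k];
          std::copy(eta_prop.begin(), eta_prop.end(), eta.begin());
          std::copy(ll_prop.begin(), ll_prop.end(), ll.begin());
        }
      }
      if (gamma > 0.0) ls_joint += gamma * (a - target_joint);
    }

    // person random intercepts (independent given everything else)
    for (int j = 0; j < np; ++j) {
      const double delta = norm_rand() * std::exp(ls_u[j]);
      const std::vector<int>& rows = prows[j];
      if (scratch.size() < rows.size()) scratch.resize(rows.size());
      double dlp = 0.0;
      bool ok = true;
      for (size_t r = 0; r < rows.size(); ++r) {
        const int i = rows[r];
        const double ne = eta[i] + delta;
        if (ne >= 0.0) { ok = false; break; }
        const double lp = bern_ll(y[i], ne);
        scratch[r] = lp;
        dlp += lp - ll[i];
      }
      double a = 0.0;
      if (ok) {
        const double u0 = u[j], u1 = u[j] + delta;
        dlp += (u0 * u0 - u1 * u1) / (2.0 * sigma_p * sigma_p);
        a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < a) {
          u[j] += delta;
          for (size_t r = 0; r < rows.size(); ++r) {
            const int i = rows[r];
            eta[i] += delta;
            ll[i] = scratch[r];
          }
        }
      }
      if (gamma > 0.0) ls_u[j] += gamma * (a - target);
    }

    // cluster random intercepts
    for (int j = 0; j < nc; ++j) {
      const double delta = norm_rand() * std::exp(ls_v[j]);
      const std::vector<int>& rows = crows[j];
      if (scratch.size() < rows.size()) scratch.resize(rows.size());
      double dlp = 0.0;
      bool ok = true;
      for (size_t r = 0; r < rows.size(); ++r) {
        const int i = rows[r];
        const double ne = eta[i] + delta;
        if (ne >= 0.0) { ok = false; break; }
        const double lp = bern_ll(y[i], ne);
        scratch[r] = lp;
        dlp += lp - ll[i];
      }
      double a = 0.0;
      if (ok) {
        const double v0 = v[j], v1 = v[j] + delta;
        dlp += (v0 * v0 - v1 * v1) / (2.0 * sigma_c * sigma_c);
        a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < a) {
          v[j] += delta;
          for (size_t r = 0; r < rows.size(); ++r) {
            const int i = rows[r];
            eta[i] += delta;
            ll[i] = scratch[r];
          }
        }
      }
      if (gamma > 0.0) ls_v[j] += gamma * (a - target);
    }

    // random-effect SDs, random walk on the log scale
    double ssu = 0.0, ssv = 0.0;
    for (int j = 0; j < np; ++j) ssu += u[j] * u[j];
    for (int j = 0; j < nc; ++j) ssv += v[j] * v[j];
    {
      const double delta = norm_rand() * std::exp(ls_sp);
      const double s1 = sigma_p * std::exp(delta);
      double dlp = -np * (std::log(s1) - std::log(sigma_p))
        - ssu / 2.0 * (1.0 / (s1 * s1) - 1.0 / (sigma_p * sigma_p))
        - (s1 * s1 - sigma_p * sigma_p) / (2.0 * re_scale_p * re_scale_p)
        + delta; // Jacobian of the log transform
      const double a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
      if (unif_rand() < a) sigma_p = s1;
      if (gamma > 0.0) ls_sp += gamma * (a - target);
    }
    {
      const double delta = norm_rand() * std::exp(ls_sc);
      const double s1 = sigma_c * std::exp(delta);
      double dlp = -nc * (std::log(s1) - std::log(sigma_c))
        - ssv / 2.0 * (1.0 / (s1 * s1) - 1.0 / (sigma_c * sigma_c))
        - (s1 * s1 - sigma_c * sigma_c) / (2.0 * re_scale_c * re_scale_c)
        + delta;
      const double a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
      if (unif_rand() < a) sigma_c = s1;
      if (gamma > 0.0) ls_sc += gamma * (a - target);
    }

    // group-scale move for (u, sigma_p): u -> c u, sigma_p -> c sigma_p.
    // In (log sigma, u/sigma) coordinates this is a symmetric random walk;
    // acceptance is L(cu)/L(u) * c * halfnormal(c sigma)/halfnormal(sigma).
    for (int rep = 0; rep < 2; ++rep) {
      const double z = norm_rand() * std::exp(ls_scale_p);
      const double c = std::exp(z);
      bool ok = true;
      double dlp = 0.0;
      for (int i = 0; i < n; ++i) {
        const double ne = eta[i] + (c - 1.0) * u[person[i]];
        if (ne >= 0.0) { ok = false; break; }
        eta_prop[i] = ne;
        const double lp = bern_ll(y[i], ne);
        ll_prop[i] = lp;
        dlp += lp - ll[i];
      }
      double a = 0.0;
      if (ok) {
        const double s1 = c * sigma_p;
        dlp += z - (s1 * s1 - sigma_p * sigma_p) / (2.0 * re_scale_p * re_scale_p);
        a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < a) {
          for (int j = 0; j < np; ++j) u[j] *= c;
          sigma_p = s1;
          std::copy(eta_prop.begin(), eta_prop.end(), eta.begin());
          std::copy(ll_prop.begin(), ll_prop.end(), ll.begin());
        }
      }
      if (gamma > 0.0) ls_scale_p += gamma * (a - target);
    }
    // group-scale move for (v, sigma_c)
    for (int rep = 0; rep < 2; ++rep) {
      const double z = norm_rand() * std::exp(ls_scale_c);
      const double c = std::exp(z);
      bool ok = true;
      double dlp = 0.0;
      for (int i = 0; i < n; ++i) {
        const double ne = eta[i] + (c - 1.0) * v[cluster[i]];
        if (ne >= 0.0) { ok = false; break; }
        eta_prop[i] = ne;
        const double lp = bern_ll(y[i], ne);
        ll_prop[i] = lp;
        dlp += lp - ll[i];
      }
      double a = 0.0;
      if (ok) {
        const double s1 = c * sigma_c;
        dlp += z - (s1 * s1 - sigma_c * sigma_c) / (2.0 * re_scale_c * re_scale_c);
        a = dlp >= 0.0 ? 1.0 : std::exp(dlp);
        if (unif_rand() < a) {
          for (int j = 0; j < nc; ++j) v[j] *= c;
          sigma_c = s1;
          std::copy(eta_prop.begin(), eta_prop.end(), eta.begin());
          std::copy(ll_prop.begin(), ll_prop.end(), ll.begin());
        }
      }
      if (gamma > 0.0) ls_scale_c += gamma * (a - target);
    }

    // learn the fixed-effect covariance during burn-in
    if (t >= cov_start && t < burnin) {
      ++n_cov;
      for (int k = 0; k < p; ++k) {
        const double d = beta[k] - cov_mean[k];
        cov_mean[k] += d / n_cov;
        for (int j = 0; j <= k; ++j)
          cov_M2[k * p + j] += d * (beta[j] - cov_mean[j]);
      }
      if (n_cov > 10L * p && (t % 25 == 0 || t == burnin - 1)) {
        std::vector<double> C(p * p);
        for (int k = 0; k < p; ++k)
          for (int j = 0; j <= k; ++j) {
            double cv = cov_M2[k * p + j] / (n_cov - 1);
            if (k == j) cv += 1e-10;
            C[k * p + j] = C[j * p + k] = cv;
          }
        have_chol = cholesky(C, p, chol_L);
      }
    }

    if (t >= burnin && (t - burnin) % thin == 0 && stored < n_store) {
      for (int k = 0; k < p; ++k) beta_draws(stored, k) = beta[k];
      for (int j = 0; j < np; ++j) u_draws(stored, j) = u[j];
      for (int j = 0; j < nc; ++j) v_draws(stored, j) = v[j];
      sp_draws[stored] = sigma_p;
      sc_draws[stored] = sigma_c;
      ++stored;
    }
  }

  return List::create(_["beta"] = beta_draws, _["sigma_person"] = sp_draws,
                      _["sigma_cluster"] = sc_draws, _["u"] = u_draws,
                      _["v"] = v_draws);
}
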