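// Blocked adaptive Metropolis-within-Gibbs sampler for the two-group
// hierarchical LBA model with contaminant mixture.
//
// Blocks per iteration:
//   1. Individual unconstrained 17-vectors theta_i: adaptive random-walk MH
//      (empirical-covariance proposal, Robbins-Monro step-size tuning during
//      warmup, frozen afterwards), n_inner sweeps per stored iteration.
//      Each sweep also runs slice-sampling line moves along the principal
//      axes of an adapted (A, b, t0) sub-covariance: these three components
//      form a stiff ridge that the full 17-dimensional proposal traverses
//      too slowly.  Every drift, boost and start-point component is
//      additionally refreshed once per iteration by an independence
//      proposal from its conditional prior N(m_k, 1/Prec_kk), evaluated on
//      the affected rows only: for weakly informed components (error
//      drifts of near-ceiling cells) the likelihood ratio is ~1 and the
//      component decorrelates in one step.
//   2. Group means mu_g | theta, Sigma: exact conjugate Gibbs draw, plus a
//      joint translation move (mu_g and all group members' theta_i shifted
//      together; the standardized offsets are invariant, so the ratio is
//      likelihood x mu-prior only) that decouples the group level from the
//      individual level.
//   3. Shared covariance Sigma under the Huang-Wand (2013) prior
//      (Sigma | a ~ IW(nu + d - 1, 2 nu diag(1/a)), a_k ~ IG(1/2, 1/A^2)),
//      which gives the scales exact half-t(nu, 0, A) marginals: exact
//      conjugate Gibbs draws of Sigma and of the auxiliary scales a.
//      Interleaved with per-component non-centered scale moves (component k
//      of every individual rescaled about its group mean jointly with
//      Sigma's row/column k; standardized offsets invariant) that break the
//      scale funnel of weakly identified components.
//   4. Contaminant proportion lambda: random-walk MH on the logit scale using
//      cached race densities (lambda-independent), several steps per
//      iteration.
//
// All randomness comes from R's RNG, so chains are reproducible via set.seed.

#include <RcppArmadillo.h>
#include "lba.h"

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double part_loglik(const arma::vec &rt, const arma::ivec &resp,
                          const arma::ivec &mode, const arma::ivec &kw,
                          const arma::ivec &kw1c, const arma::ivec &kw2c,
                          int r0, int r1, const double *p, double lambda,
                          double tmax, double *race_buf) {
  double s = 0.0;
  for (int i = r0; i < r1; ++i) {
    s += lba_trial_loglik(rt[i], resp[i], mode[i], kw[i], kw1c[i], kw2c[i],
                          p, lambda, tmax, race_buf ? race_buf + i : nullptr);
  }
  return s;
}

static double mix_ll_from_cache(const double *race, int r0, int r1,
                                double lambda, double tmax) {
  const double c = 0.25 / tmax;
  double s = 0.0;
  for (int i = r0; i < r1; ++i) {
    double ll = std::log((1.0 - lambda) * race[i] + lambda * c);
    if (!(ll > LBA_LOG_FLOOR)) ll = LBA_LOG_FLOOR;
    s += ll;
  }
  return s;
}

static arma::vec rnorm_vec(int d) {
  arma::vec z(d);
  for (int k = 0; k < d; ++k) z[k] = R::norm_rand();
  return z;
}

static double subset_loglik(const std::vector<int> &idx, const arma::vec &rt,
                            const arma::ivec &resp, const arma::ivec &mode,
                            const arma::ivec &kw, const arma::ivec &kw1c,
                            const arma::ivec &kw2c, const double *p,
                            double lambda, double tmax, double *race_buf) {
  double s = 0.0;
  for (int r : idx)
    s += lba_trial_loglik(rt[r], resp[r], mode[r], kw[r], kw1c[r], kw2c[r],
                          p, lambda, tmax, race_buf ? race_buf + r : nullptr);
  return s;
}

static double subset_ll_from_cache(const std::vector<int> &idx,
                                   const double *race, double lambda,
                                   double tmax) {
  const double c = 0.25 / tmax;
  double s = 0.0;
  for (int r : idx) {
    double ll = std::log((1.0 - lambda) * race[r] + lambda * c);
    if (!(ll > LBA_LOG_FLOOR)) ll = LBA_LOG_FLOOR;
    s += ll;
  }
  return s;
}

// [[Rcpp::export(name = ".run_lba_chain_cpp")]]
List run_lba_chain_cpp(List rows, IntegerVector row_start, IntegerVector group,
                       double tmax, int n_warmup, int n_save, int n_thin,
                       int n_inner,
                       int n_lambda_steps, List init, List prior,
                       double target_accept) {
  const arma::vec rt = as<arma::vec>(rows["rt"]);
  const arma::ivec resp = as<arma::ivec>(rows["resp"]);
  const arma::ivec mode = as<arma::ivec>(rows["mode"]);
  const arma::ivec kw = as<arma::ivec>(rows["kw"]);
  const arma::ivec kw1c = as<arma::ivec>(rows["kw1c"]);
  const arma::ivec kw2c = as<arma::ivec>(rows["kw2c"]);

  const int d = 17;
  const int n = group.size();
  const int n_rows = rt.n_elem;

  const double mu_sd = prior["mu_sd"];
  const double tau_df = prior["tau_df"];
  const double tau_scale = prior["tau_scale"];
  const double lam_a = prior["lambda_a"];
  const double lam_b = prior["lambda_b"];
  const double hw_nu = tau_df;       // half-t df of the scale marginals
  const double hw_A = tau_scale;     // half-t scale of the scale marginals

  // state
  arma::mat theta = as<arma::mat>(init["theta"]);   // n x d, unconstrained
  arma::mat mu = as<arma::mat>(init["mu"]);         // 2 x d
  arma::mat Sigma = as<arma::mat>(init["Sigma"]);   // d x d
  double lambda = init["lambda"];
  arma::vec a_aux(d, arma::fill::ones);  // Huang-Wand auxiliary scales

  arma::mat Prec = arma::inv_sympd(Sigma);
  double logdet_sigma;
  {
    double sign;
    arma::log_det(logdet_sigma, sign, Sigma);
  }

  arma::ivec ng(2, arma::fill::zeros);
  for (int i = 0; i < n; ++i) ng[group[i]] += 1;

  // caches
  std::vector<double> race(n_rows, 0.0), race_prop(n_rows, 0.0);
  // per participant: rows affected by each drift block (mode) and by the
  // boost parameters -- used to localize the component-refresh likelihoods
  std::vector<std::array<std::vector<int>, 3>> mode_rows(n);
  std::vector<std::vector<int>> kw2_rows(n), kw3_rows(n);
  for (int i = 0; i < n; ++i) {
    for (int r = row_start[i]; r < row_start[i + 1]; ++r) {
      mode_rows[i][mode[r] - 1].push_back(r);
      if (kw[r] == 2) kw2_rows[i].push_back(r);
      if (kw[r] == 3) kw3_rows[i].push_back(r);
    }
  }
  arma::vec cur_ll(n);
  for (int i = 0; i < n; ++i) {
    double p[17];
    arma::rowvec th_i = theta.row(i);
    lba_constrain(th_i.memptr(), p);
    cur_ll[i] = part_loglik(rt, resp, mode, kw, kw1c, kw2c, row_start[i],
                            row_start[i + 1], p, lambda, tmax, race.data());
  }

  // adaptation state
  arma::vec log_step(n, arma::fill::value(std::log(0.10)));
  std::vector<arma::mat> prop_chol(n, arma::eye(d, d));
  // principal axes of the adapted (A, b, t0) covariance, scaled to 1 SD:
  // used for slice-sampling line moves along the stiff ridge
  std::vector<arma::mat> sub_axes(n, 0.1 * arma::eye(3, 3));
  const arma::uvec sub_idx = {14, 15, 16};  // A, b, t0 (unconstrained)
  arma::mat run_mean(n, d, arma::fill::zeros);
  std::vector<arma::mat> run_m2(n, arma::mat(d, d, arma::fill::zeros));
  int run_count = 0;
  double lam_log_step = std::log(0.3);
  arma::vec scale_log_step(d, arma::fill::value(std::log(0.10)));
  arma::vec shift_log_step(2, arma::fill::value(std::log(0.05)));
  arma::vec ridge_log_step(2, arma::fill::value(std::log(0.02)));
  std::vector<arma::mat> shift_chol(2, arma::eye(d, d));
  arma::mat run_mean_mu(2, d, arma::fill::zeros);
  std::vector<arma::mat> run_m2_mu(2, arma::mat(d, d, arma::fill::zeros));

  // output
  arma::mat out_mu(n_save, 2 * d);
  arma::mat out_tau(n_save, d);
  arma::mat out_corr(n_save, d * (d - 1) / 2);
  arma::vec out_lambda(n_save);
  arma::mat out_theta(n_save, n * d);
  double acc_theta = 0.0, acc_sigma = 0.0, acc_lambda = 0.0;
  long n_prop_theta = 0, n_prop_sigma = 0, n_prop_lambda = 0;

  const int n_iter = n_warmup + n_save * n_thin;
  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool warm = iter <= n_warmup;

    // ---- 1. individual parameters -------------------------------------
    for (int sweep = 0; sweep < n_inner; ++sweep) {
      for (int i = 0; i < n; ++i) {
        const int g = group[i];
        arma::rowvec th = theta.row(i);
        arma::vec eps = prop_chol[i] * rnorm_vec(d) * std::exp(log_step[i]);
        arma::rowvec th_prop = th + eps.t();

        double p_prop[17];
        lba_constrain(th_prop.memptr(), p_prop);
        const double ll_prop =
            part_loglik(rt, resp, mode, kw, kw1c, kw2c, row_start[i],
                        row_start[i + 1], p_prop, lambda, tmax,
                        race_prop.data());

        arma::vec dc = (th - mu.row(g)).t();
        arma::vec dp = (th_prop - mu.row(g)).t();
        const double lp_cur = cur_ll[i] - 0.5 * arma::dot(dc, Prec * dc);
        const double lp_prop = ll_prop - 0.5 * arma::dot(dp, Prec * dp);

        const double la = lp_prop - lp_cur;
        const double acc_p = la >= 0.0 ? 1.0 : std::exp(la);
        if (std::log(R::unif_rand()) < la) {
          theta.row(i) = th_prop;
          cur_ll[i] = ll_prop;
          for (int r = row_start[i]; r < row_start[i + 1]; ++r)
            race[r] = race_prop[r];
        }
        if (warm) {
          const double t = static_cast<double>((iter - 1) * n_inner + sweep + 1);
          log_step[i] += (acc_p - target_accept) * std::min(0.3, 3.0 / std::sqrt(t));
        } else {
          acc_theta += acc_p;
          ++n_prop_theta;
        }
      }
    }

    // (A, b, t0) line moves: slice sampling along principal axes of the
    // adapted sub-covariance — the dominant axis (the stiff ridge) every
    // iteration, plus one of the two minor axes in rotation
    {
      const int minor_ax = (iter % 2 == 0) ? 0 : 1;
      for (int i = 0; i < n; ++i) {
        const int g = group[i];
        for (const int ax : {2, minor_ax}) {
          arma::rowvec th2 = theta.row(i);
          arma::rowvec dir(d, arma::fill::zeros);
          for (int k = 0; k < 3; ++k) dir[sub_idx[k]] = sub_axes[i](k, ax);
          arma::rowvec th2_prop = th2;
          double p2[17];
          double ll_last = 0.0;
          const auto logf = [&](double t, double *race_buf) {
            th2_prop = th2 + t * dir;
            lba_constrain(th2_prop.memptr(), p2);
            ll_last = part_loglik(rt, resp, mode, kw, kw1c, kw2c,
                                  row_start[i], row_start[i + 1], p2, lambda,
                                  tmax, race_buf);
            arma::vec dv = (th2_prop - mu.row(g)).t();
            return ll_last - 0.5 * arma::dot(dv, Prec * dv);
          };
          arma::vec dv0 = (th2 - mu.row(g)).t();
          const double lf0 = cur_ll[i] - 0.5 * arma::dot(dv0, Prec * dv0);
          const double y = lf0 + std::log(R::unif_rand());
          double lo = -R::unif_rand();
          double hi = lo + 1.0;
          for (int s = 0; s < 3 && logf(lo, nullptr) > y; ++s) lo -= 1.0;
          for (int s = 0; s < 3 && logf(hi, nullptr) > y; ++s) hi += 1.0;
          for (int s = 0; s < 30; ++s) {
            const double t1 = lo + (hi - lo) * R::unif_rand();
            if (logf(t1, race_prop.data()) > y) {
              theta.row(i) = th2_prop;
              cur_ll[i] = ll_last;
              for (int r = row_start[i]; r < row_start[i + 1]; ++r)
                race[r] = race_prop[r];
              break;
            }
            if (t1 < 0) lo = t1; else hi = t1;
            if (hi - lo < 1e-12) break;
          }
        }
      }
    }

    // conditional-prior refresh: every drift, boost and start-point-range
    // component of every participant, once per iteration.  Proposals come
    // from the conditional prior N(m_k, 1/Prec_kk); the prior terms cancel
    // exactly, so acceptance is the likelihood ratio over the affected
    // rows only (a drift touches its mode's rows; a boost its keyword's
    // rows).  Weakly informed components decorrelate in one step.
    for (int i = 0; i < n; ++i) {
      const int g = group[i];
      for (int k = 0; k < 15; ++k) {  // skip b, t0 (handled by line slices)
        const std::vector<int> *aff;
        std::vector<int> all_rows;
        if (k < 12) {
          aff = &mode_rows[i][k / 4];
        } else if (k == 12) {
          aff = &kw2_rows[i];
        } else if (k == 13) {
          aff = &kw3_rows[i];
        } else {
          all_rows.reserve(row_start[i + 1] - row_start[i]);
          for (int r = row_start[i]; r < row_start[i + 1]; ++r)
            all_rows.push_back(r);
          aff = &all_rows;
        }
        if (aff->empty()) continue;
        arma::rowvec th = theta.row(i);
        double m = mu(g, k);
        for (int j = 0; j < d; ++j) {
          if (j == k) continue;
          m -= Prec(k, j) * (th[j] - mu(g, j)) / Prec(k, k);
        }
        arma::rowvec th_prop = th;
        th_prop[k] = m + R::norm_rand() / std::sqrt(Prec(k, k));
        double p_prop[17];
        lba_constrain(th_prop.memptr(), p_prop);
        const double old_sub =
            subset_ll_from_cache(*aff, race.data(), lambda, tmax);
        const double new_sub =
            subset_loglik(*aff, rt, resp, mode, kw, kw1c, kw2c, p_prop,
                          lambda, tmax, race_prop.data());
        if (std::log(R::unif_rand()) < new_sub - old_sub) {
          theta.row(i) = th_prop;
          cur_ll[i] += new_sub - old_sub;
          for (int r : *aff) race[r] = race_prop[r];
        }
      }
    }

    // warmup covariance adaptation (one sample per stored iteration).
    // The accumulators restart at 25% and 50% of warmup so the final
    // proposal shape reflects the near-stationary chain, not the approach
    // path from the random initial values.
    if (warm) {
      if (iter == n_warmup / 4 || iter == n_warmup / 2) {
        run_count = 0;
        run_mean.zeros();
        for (int i = 0; i < n; ++i) run_m2[i].zeros();
        run_mean_mu.zeros();
        for (int g = 0; g < 2; ++g) run_m2_mu[g].zeros();
      }
      ++run_count;
      for (int i = 0; i < n; ++i) {
        arma::rowvec x = theta.row(i);
        arma::rowvec delta = x - run_mean.row(i);
        run_mean.row(i) += delta / run_count;
        run_m2[i] += delta.t() * (x - run_mean.row(i));
      }
      if (run_count >= 100 && run_count % 25 == 0) {
        for (int i = 0; i < n; ++i) {
          arma::mat cov = run_m2[i] / (run_count - 1);
          cov.diag() += 1e-6;
          arma::mat L;
          if (arma::chol(L, (5.6644 / d) * cov, "lower")) prop_chol[i] = L;
          arma::mat cov3 = cov.submat(sub_idx, sub_idx);
          arma::vec ev;
          arma::mat V;
          if (arma::eig_sym(ev, V, cov3)) {
            for (int k = 0; k < 3; ++k)
              V.col(k) *= std::sqrt(std::max(ev[k], 1e-10));
            sub_axes[i] = V;
          }
        }
      }
    }

    // ---- 2. group means (conjugate Gibbs) ------------------------------
    for (int g = 0; g < 2; ++g) {
      arma::mat prec_post = ng[g] * Prec;
      prec_post.diag() += 1.0 / (mu_sd * mu_sd);
      arma::vec sum_theta(d, arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        if (group[i] == g) sum_theta += theta.row(i).t();
      arma::vec mean_post = arma::solve(prec_post, Prec * sum_theta,
                                        arma::solve_opts::likely_sympd);
      arma::mat U = arma::chol(prec_post);  // upper
      arma::vec z = rnorm_vec(d);
      mu.row(g) = (mean_post + arma::solve(arma::trimatu(U), z)).t();
    }

    // ---- 2b. group translation moves ------------------------------------
    for (int g = 0; g < 2; ++g) {
      if (ng[g] == 0) continue;
      for (int rep = 0; rep < 1; ++rep) {
        arma::vec delta = shift_chol[g] * rnorm_vec(d) *
                          std::exp(shift_log_step[g]);
        double la = 0.0;
        arma::rowvec mu_prop = mu.row(g) + delta.t();
        for (int k = 0; k < d; ++k) {
          la += R::dnorm(mu_prop[k], 0.0, mu_sd, 1) -
                R::dnorm(mu(g, k), 0.0, mu_sd, 1);
        }
        std::vector<double> ll_prop_i(n, 0.0);
        for (int i = 0; i < n; ++i) {
          if (group[i] != g) continue;
          arma::rowvec th_prop = theta.row(i) + delta.t();
          double p_prop[17];
          lba_constrain(th_prop.memptr(), p_prop);
          ll_prop_i[i] = part_loglik(rt, resp, mode, kw, kw1c, kw2c,
                                     row_start[i], row_start[i + 1], p_prop,
                                     lambda, tmax, race_prop.data());
          la += ll_prop_i[i] - cur_ll[i];
        }
        const double acc_p = la >= 0.0 ? 1.0 : std::exp(la);
        if (std::log(R::unif_rand()) < la) {
          mu.row(g) = mu_prop;
          for (int i = 0; i < n; ++i) {
            if (group[i] != g) continue;
            theta.row(i) += delta.t();
            cur_ll[i] = ll_prop_i[i];
            for (int r = row_start[i]; r < row_start[i + 1]; ++r)
              race[r] = race_prop[r];
          }
        }
        if (warm) {
          const double t = static_cast<double>(2 * (iter - 1) + rep + 1);
          shift_log_step[g] += (acc_p - target_accept) *
                               std::min(0.3, 3.0 / std::sqrt(t));
        }
      }

      // group scaling move along the soft scale ridge of near-ceiling
      // cells: drifts and boosts of the group mean and of every member
      // scale by c while log A and log(b - A) translate by log c.  With
      // equal start/threshold scaling and c-scaled drift means the race is
      // invariant except through the s = 1 constraint, which identifies
      // the scale only weakly at high accuracy -- without this move the
      // posterior along the ridge is explored far too slowly.  The theta
      // prior does not cancel (tau is shared across groups), so the MVN
      // terms are evaluated explicitly; the Jacobian is c^(14 (n_g + 1)).
      for (int rep = 0; rep < 2; ++rep) {
        const double eps = std::exp(ridge_log_step[g]) * R::norm_rand();
        const double c = std::exp(eps);
        arma::rowvec mu_prop = mu.row(g);
        for (int k = 0; k < 14; ++k) mu_prop[k] *= c;
        mu_prop[14] += eps;
        mu_prop[15] += eps;
        double la = 14.0 * (ng[g] + 1.0) * eps;
        for (int k = 0; k < d; ++k)
          la += R::dnorm(mu_prop[k], 0.0, mu_sd, 1) -
                R::dnorm(mu(g, k), 0.0, mu_sd, 1);
        std::vector<double> ll_prop_i(n, 0.0);
        arma::mat th_prop_all(n, d);
        for (int i = 0; i < n; ++i) {
          if (group[i] != g) continue;
          arma::rowvec th_prop = theta.row(i);
          for (int k = 0; k < 14; ++k) th_prop[k] *= c;
          th_prop[14] += eps;
          th_prop[15] += eps;
          th_prop_all.row(i) = th_prop;
          double p_prop[17];
          lba_constrain(th_prop.memptr(), p_prop);
          ll_prop_i[i] = part_loglik(rt, resp, mode, kw, kw1c, kw2c,
                                     row_start[i], row_start[i + 1], p_prop,
                                     lambda, tmax, race_prop.data());
          la += ll_prop_i[i] - cur_ll[i];
          arma::vec dn = (th_prop - mu_prop).t();
          arma::vec dc = (theta.row(i) - mu.row(g)).t();
          la += -0.5 * arma::dot(dn, Prec * dn) + 0.5 * arma::dot(dc, Prec * dc);
        }
        const double acc_p = la >= 0.0 ? 1.0 : std::exp(la);
        if (std::log(R::unif_rand()) < la) {
          mu.row(g) = mu_prop;
          for (int i = 0; i < n; ++i) {
            if (group[i] != g) continue;
            theta.row(i) = th_prop_all.row(i);
            cur_ll[i] = ll_prop_i[i];
            for (int r2 = row_start[i]; r2 < row_start[i + 1]; ++r2)
              race[r2] = race_prop[r2];
          }
        }
        if (warm) {
          const double t = static_cast<double>(2 * (iter - 1) + rep + 1);
          ridge_log_step[g] += (acc_p - 0.30) * std::min(0.3, 3.0 / std::sqrt(t));
        }
      }

      // randomized drift/boost group-translation slices: three components
      // per group per iteration, localized to the rows the component
      // touches; over iterations every drift's common mode is covered
      for (int rep = 0; rep < 3; ++rep) {
        const int kk = static_cast<int>(R::unif_rand() * 14.0);
        std::vector<double> delta_i(n, 0.0);
        const auto logf = [&](double delta) {
          double ll = 0.0;
          for (int i = 0; i < n; ++i) {
            if (group[i] != g) continue;
            const std::vector<int> &aff =
                kk < 12 ? mode_rows[i][kk / 4]
                        : (kk == 12 ? kw2_rows[i] : kw3_rows[i]);
            if (aff.empty()) continue;
            arma::rowvec th_prop = theta.row(i);
            th_prop[kk] += delta;
            double p_prop[17];
            lba_constrain(th_prop.memptr(), p_prop);
            const double new_sub =
                subset_loglik(aff, rt, resp, mode, kw, kw1c, kw2c, p_prop,
                              lambda, tmax, race_prop.data());
            delta_i[i] = new_sub -
                subset_ll_from_cache(aff, race.data(), lambda, tmax);
            ll += delta_i[i];
          }
          return ll + R::dnorm(mu(g, kk) + delta, 0.0, mu_sd, 1);
        };
        const double lf0 = R::dnorm(mu(g, kk), 0.0, mu_sd, 1);
        const double y = lf0 + std::log(R::unif_rand());
        const double w = std::sqrt(Sigma(kk, kk) / ng[g]);
        double lo = -w * R::unif_rand();
        double hi = lo + w;
        for (int s = 0; s < 3 && logf(lo) > y; ++s) lo -= w;
        for (int s = 0; s < 3 && logf(hi) > y; ++s) hi += w;
        for (int s = 0; s < 30; ++s) {
          const double t1 = lo + (hi - lo) * R::unif_rand();
          if (logf(t1) > y) {
            mu(g, kk) += t1;
            for (int i = 0; i < n; ++i) {
              if (group[i] != g) continue;
              theta(i, kk) += t1;
              cur_ll[i] += delta_i[i];
              const std::vector<int> &aff =
                  kk < 12 ? mode_rows[i][kk / 4]
                          : (kk == 12 ? kw2_rows[i] : kw3_rows[i]);
              for (int r : aff) race[r] = race_prop[r];
            }
            break;
          }
          if (t1 < 0) lo = t1; else hi = t1;
          if (hi - lo < 1e-12) break;
        }
      }

      // caution-preserving A-jumps: the start-point range A is only weakly
      // identified at desk scale and the posterior can be bimodal (a mode
      // with generative A and a boundary mode with A ~ 0, t0 at the floor,
      // shifted b and drifts).  Large joint proposals on u_A for the group
      // mean and every member, with u_b adjusted so the caution b - A/2 is
      // invariant (the likelihood's flattest direction), let a chain cross
      // between modes.  Jacobian: prod exp(u_b) / exp(u_b'); proposals
      // that would require b' <= A' (negative threshold gap) are rejected.
      for (int rep = 0; rep < 2; ++rep) {
        const double delta = 1.0 * R::norm_rand();
        double la = 0.0;
        bool ok = true;
        arma::rowvec mu_prop = mu.row(g);
        std::vector<double> ll_prop_i(n, 0.0);
        arma::mat th_prop_all(n, d);
        const auto transform = [&](arma::rowvec &v) {
          const double A_old = std::exp(v[14]);
          const double A_new = std::exp(v[14] + delta);
          const double gap_new = std::exp(v[15]) + (A_old - A_new) / 2.0;
          if (gap_new <= 1e-10) return false;
          la += v[15] - std::log(gap_new);  // log Jacobian contribution
          v[14] += delta;
          v[15] = std::log(gap_new);
          return true;
        };
        ok = transform(mu_prop);
        if (ok) {
          for (int k = 0; k < d; ++k)
            la += R::dnorm(mu_prop[k], 0.0, mu_sd, 1) -
                  R::dnorm(mu(g, k), 0.0, mu_sd, 1);
          for (int i = 0; i < n && ok; ++i) {
            if (group[i] != g) continue;
            arma::rowvec th_prop = theta.row(i);
            if (!transform(th_prop)) { ok = false; break; }
            th_prop_all.row(i) = th_prop;
            double p_prop[17];
            lba_constrain(th_prop.memptr(), p_prop);
            ll_prop_i[i] = part_loglik(rt, resp, mode, kw, kw1c, kw2c,
                                       row_start[i], row_start[i + 1],
                                       p_prop, lambda, tmax,
                                       race_prop.data());
            la += ll_prop_i[i] - cur_ll[i];
            arma::vec dn = (th_prop - mu_prop).t();
            arma::vec dc = (theta.row(i) - mu.row(g)).t();
            la += -0.5 * arma::dot(dn, Prec * dn) +
                  0.5 * arma::dot(dc, Prec * dc);
          }
        }
        if (ok && std::log(R::unif_rand()) < la) {
          mu.row(g) = mu_prop;
          for (int i = 0; i < n; ++i) {
            if (group[i] != g) continue;
            theta.row(i) = th_prop_all.row(i);
            cur_ll[i] = ll_prop_i[i];
            for (int r2 = row_start[i]; r2 < row_start[i + 1]; ++r2)
              race[r2] = race_prop[r2];
          }
        }
      }

      // per-component group translation slices for A and t0: the common
      // mode of (mu_gk, theta_ik for the group) is the slowest direction
      // of the centered hierarchy for these likelihood-stiff components;
      // offsets and S are invariant, so only the group likelihood and the
      // mu prior enter.  Slice sampling needs no tuned step.
      for (const int kk : {14, 16}) {
        std::vector<double> ll_buf(n, 0.0);
        const auto logf = [&](double delta) {
          double ll = 0.0;
          for (int i = 0; i < n; ++i) {
            if (group[i] != g) continue;
            arma::rowvec th_prop = theta.row(i);
            th_prop[kk] += delta;
            double p_prop[17];
            lba_constrain(th_prop.memptr(), p_prop);
            ll_buf[i] = part_loglik(rt, resp, mode, kw, kw1c, kw2c,
                                    row_start[i], row_start[i + 1], p_prop,
                                    lambda, tmax, race_prop.data());
            ll += ll_buf[i];
          }
          return ll + R::dnorm(mu(g, kk) + delta, 0.0, mu_sd, 1);
        };
        double ll_g0 = 0.0;
        for (int i = 0; i < n; ++i)
          if (group[i] == g) ll_g0 += cur_ll[i];
        const double lf0 = ll_g0 + R::dnorm(mu(g, kk), 0.0, mu_sd, 1);
        const double y = lf0 + std::log(R::unif_rand());
        const double w = std::sqrt(Sigma(kk, kk) / ng[g]);
        double lo = -w * R::unif_rand();
        double hi = lo + w;
        for (int s = 0; s < 3 && logf(lo) > y; ++s) lo -= w;
        for (int s = 0; s < 3 && logf(hi) > y; ++s) hi += w;
        for (int s = 0; s < 30; ++s) {
          const double t1 = lo + (hi - lo) * R::unif_rand();
          if (logf(t1) > y) {
            mu(g, kk) += t1;
            for (int i = 0; i < n; ++i) {
              if (group[i] != g) continue;
              theta(i, kk) += t1;
              cur_ll[i] = ll_buf[i];
              for (int r = row_start[i]; r < row_start[i + 1]; ++r)
                race[r] = race_prop[r];
            }
            break;
          }
          if (t1 < 0) lo = t1; else hi = t1;
          if (hi - lo < 1e-12) break;
        }
      }
    }
    if (warm) {
      for (int g = 0; g < 2; ++g) {
        arma::rowvec x = mu.row(g);
        arma::rowvec delta = x - run_mean_mu.row(g);
        run_mean_mu.row(g) += delta / run_count;
        run_m2_mu[g] += delta.t() * (x - run_mean_mu.row(g));
      }
      if (run_count >= 100 && run_count % 25 == 0) {
        for (int g = 0; g < 2; ++g) {
          arma::mat cov = run_m2_mu[g] / (run_count - 1);
          cov.diag() += 1e-6;
          arma::mat L;
          if (arma::chol(L, (5.6644 / d) * cov, "lower")) shift_chol[g] = L;
        }
      }
    }

    // ---- 3. covariance (Huang-Wand conjugate Gibbs) ---------------------
    {
      arma::mat S(d, d, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        arma::vec dv = (theta.row(i) - mu.row(group[i])).t();
        S += dv * dv.t();
      }
      // Sigma | a, theta, mu ~ IW(hw_nu + d - 1 + n, 2 hw_nu diag(1/a) + S)
      arma::mat Sp = S;
      for (int k = 0; k < d; ++k) Sp(k, k) += 2.0 * hw_nu / a_aux[k];
      const double nu_post = hw_nu + d - 1.0 + n;

      // Bartlett draw W ~ Wishart(nu_post, Sp^-1); Sigma = W^-1
      arma::mat Usp = arma::chol(Sp);  // Sp = Usp' Usp
      arma::mat T = arma::solve(arma::trimatu(Usp), arma::eye(d, d));
      arma::mat Abar(d, d, arma::fill::zeros);
      for (int k = 0; k < d; ++k) {
        Abar(k, k) = std::sqrt(R::rchisq(nu_post - k));
        for (int j = 0; j < k; ++j) Abar(k, j) = R::norm_rand();
      }
      arma::mat TA = T * Abar;
      Prec = TA * TA.t();
      Sigma = arma::inv_sympd(Prec);
      {
        double sign;
        arma::log_det(logdet_sigma, sign, Sigma);
      }
      // a_k | Sigma ~ IG((hw_nu + d)/2, hw_nu * Prec_kk + 1/A^2)
      for (int k = 0; k < d; ++k) {
        const double rate = hw_nu * Prec(k, k) + 1.0 / (hw_A * hw_A);
        a_aux[k] = rate / R::rgamma((hw_nu + d) / 2.0, 1.0);
      }
      if (!warm) {
        ++n_prop_sigma;
        acc_sigma += 1.0;  // exact Gibbs draw
      }
    }

    // ---- 3b. non-centered component scale moves -------------------------
    // Rescale component k of every theta_i about its group mean by c while
    // scaling Sigma's row/column k by c AND the Huang-Wand auxiliary
    // a_k by 1/c^2.  The standardized offsets are invariant, the theta
    // prior cancels against the theta Jacobian, and the joint a_k scaling
    // keeps the IW trace term invariant, so only the likelihood, the
    // IG(1/2, 1/A^2) density of a_k and a residual log c survive:
    //   log alpha = dloglik + log c - (c^2 - 1) / (A^2 a_k)
    // (without the joint a_k move the conditional IW slice is ~6x narrower
    // than the half-t marginal and tau mixes through a second funnel)
    {
      for (int k = 0; k < d; ++k) {
        const int reps = 1;
        for (int rep = 0; rep < reps; ++rep) {
          const double eps = std::exp(scale_log_step[k]) * R::norm_rand();
          const double c = std::exp(eps);
          double dll = 0.0;
          std::vector<double> delta_i(n, 0.0);
          for (int i = 0; i < n; ++i) {
            arma::rowvec th_prop = theta.row(i);
            const double m = mu(group[i], k);
            th_prop[k] = m + c * (th_prop[k] - m);
            double p_prop[17];
            lba_constrain(th_prop.memptr(), p_prop);
            if (k < 14) {
              const std::vector<int> &aff =
                  k < 12 ? mode_rows[i][k / 4]
                         : (k == 12 ? kw2_rows[i] : kw3_rows[i]);
              if (aff.empty()) continue;
              const double old_sub =
                  subset_ll_from_cache(aff, race.data(), lambda, tmax);
              const double new_sub =
                  subset_loglik(aff, rt, resp, mode, kw, kw1c, kw2c, p_prop,
                                lambda, tmax, race_prop.data());
              delta_i[i] = new_sub - old_sub;
            } else {
              const double ll_new =
                  part_loglik(rt, resp, mode, kw, kw1c, kw2c, row_start[i],
                              row_start[i + 1], p_prop, lambda, tmax,
                              race_prop.data());
              delta_i[i] = ll_new - cur_ll[i];
            }
            dll += delta_i[i];
          }
          const double la = dll + eps -
              (c * c - 1.0) / (hw_A * hw_A * a_aux[k]);
          const double acc_p = la >= 0.0 ? 1.0 : std::exp(la);
          if (std::log(R::unif_rand()) < la) {
            for (int i = 0; i < n; ++i) {
              const double m = mu(group[i], k);
              theta(i, k) = m + c * (theta(i, k) - m);
              cur_ll[i] += delta_i[i];
              if (k < 14) {
                const std::vector<int> &aff =
                    k < 12 ? mode_rows[i][k / 4]
                           : (k == 12 ? kw2_rows[i] : kw3_rows[i]);
                for (int r : aff) race[r] = race_prop[r];
              } else {
                for (int r = row_start[i]; r < row_start[i + 1]; ++r)
                  race[r] = race_prop[r];
              }
            }
            Sigma.row(k) *= c;
            Sigma.col(k) *= c;
            Prec.row(k) /= c;
            Prec.col(k) /= c;
            logdet_sigma += 2.0 * eps;
            a_aux[k] /= c * c;
          }
          if (warm) {
            const double t = static_cast<double>(reps * (iter - 1) + rep + 1);
            scale_log_step[k] +=
                (acc_p - 0.44) * std::min(0.3, 3.0 / std::sqrt(t));
          }
        }
      }
    }

    // ---- 4. contaminant proportion -------------------------------------
    {
      double cur_mix = mix_ll_from_cache(race.data(), 0, n_rows, lambda, tmax);
      double logit_l = std::log(lambda) - std::log1p(-lambda);
      for (int s = 0; s < n_lambda_steps; ++s) {
        const double logit_prop = logit_l + std::exp(lam_log_step) * R::norm_rand();
        const double lam_prop = 1.0 / (1.0 + std::exp(-logit_prop));
        const double mix_prop =
            mix_ll_from_cache(race.data(), 0, n_rows, lam_prop, tmax);
        // Beta(a, b) prior plus logit-transform Jacobian
        const double lp_prop = mix_prop + lam_a * std::log(lam_prop) +
                               lam_b * std::log1p(-lam_prop);
        const double lp_cur = cur_mix + lam_a * std::log(lambda) +
                              lam_b * std::log1p(-lambda);
        const double la = lp_prop - lp_cur;
        const double acc_p = la >= 0.0 ? 1.0 : std::exp(la);
        if (std::log(R::unif_rand()) < la) {
          lambda = lam_prop;
          logit_l = logit_prop;
          cur_mix = mix_prop;
        }
        if (warm) {
          const double t = static_cast<double>((iter - 1) * n_lambda_steps + s + 1);
          lam_log_step += (acc_p - 0.44) * std::min(0.3, 3.0 / std::sqrt(t));
        } else {
          acc_lambda += acc_p;
          ++n_prop_lambda;
        }
      }
      // refresh cached participant likelihoods under the new lambda
      for (int i = 0; i < n; ++i)
        cur_ll[i] = mix_ll_from_cache(race.data(), row_start[i],
                                      row_start[i + 1], lambda, tmax);
    }

    // ---- store (every n_thin-th post-warmup state) ----------------------
    if (!warm && (iter - n_warmup) % n_thin == 0) {
      const int s = (iter - n_warmup) / n_thin - 1;
      for (int g = 0; g < 2; ++g)
        for (int k = 0; k < d; ++k) out_mu(s, g * d + k) = mu(g, k);
      arma::vec tau_cur = arma::sqrt(Sigma.diag());
      for (int k = 0; k < d; ++k) out_tau(s, k) = tau_cur[k];
      int idx = 0;
      for (int j = 0; j < d; ++j)
        for (int i2 = j + 1; i2 < d; ++i2)
          out_corr(s, idx++) = Sigma(i2, j) / (tau_cur[i2] * tau_cur[j]);
      out_lambda[s] = lambda;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < d; ++k) out_theta(s, i * d + k) = theta(i, k);
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["mu"] = out_mu, _["tau"] = out_tau, _["corr"] = out_corr,
      _["lambda"] = out_lambda, _["theta"] = out_theta,
      _["accept"] = List::create(
          _["theta"] = n_prop_theta ? acc_theta / n_prop_theta : NA_REAL,
          _["sigma"] = n_prop_sigma ? acc_sigma / n_prop_sigma : NA_REAL,
          _["lambda"] = n_prop_lambda ? acc_lambda / n_prop_lambda : NA_REAL));
}
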