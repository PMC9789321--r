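#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical Beta
// regression on (0,1) dissimilarities:
//   y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)
//   logit(mu_i) = alpha + sum_f scale_f * z[f][level_f(i)]
// Varying factors use the non-centered parameterization: z ~ Normal(0,1)
// and scale_f = sigma_f with sigma_f ~ Exponential(rate) sampled on the log
// scale (Jacobian-corrected). A fixed factor has scale_f = 1 and its z's
// are unpooled coefficients with Normal(0, 1) prior, which is the same
// update. alpha ~ Normal(0,1); phi ~ Gamma(shape, rate), sampled on the
// log scale. Proposal scales adapt during warmup toward ~30% acceptance
// (Robbins-Monro on the log scale) and are frozen afterwards.

static inline double ll_point(double eta, double phi, double logy,
                              double log1my) {
  double mu = 1.0 / (1.0 + std::exp(-eta));
  double a = mu * phi, b = (1.0 - mu) * phi;
  if (a <= 0.0 || b <= 0.0) return R_NegInf;
  return std::lgamma(phi) - std::lgamma(a) - std::lgamma(b) +
         (a - 1.0) * logy + (b - 1.0) * log1my;
}

// [[Rcpp::export(name = ".run_beta_chain")]]
List run_beta_chain(NumericVector y, IntegerMatrix levels,
                    IntegerVector n_levels, LogicalVector is_varying,
                    int iter, int warmup,
                    double sigma_rate, double phi_shape, double phi_rate,
                    double target_accept = 0.30) {
  const int N = y.size();
  const int F = n_levels.size();
  std::vector<double> logy(N), log1my(N);
  for (int i = 0; i < N; ++i) {
    logy[i] = std::log(y[i]);
    log1my[i] = std::log1p(-y[i]);
  }

  // observation index lists per factor level
  std::vector<std::vector<std::vector<int>>> idx(F);
  for (int f = 0; f < F; ++f) {
    idx[f].assign(n_levels[f], std::vector<int>());
    for (int i = 0; i < N; ++i) idx[f][levels(i, f)].push_back(i);
  }

  // state
  double alpha = 0.1 * norm_rand();
  std::vector<std::vector<double>> z(F);
  std::vector<double> ls(F, 0.0);  // log sigma (varying factors only)
  for (int f = 0; f < F; ++f) {
    z[f].assign(n_levels[f], 0.0);
    for (int j = 0; j < n_levels[f]; ++j) z[f][j] = 0.1 * norm_rand();
    ls[f] = std::log(0.5) + 0.2 * norm_rand();
  }
  double lphi = std::log(5.0) + 0.2 * norm_rand();

  auto scale_of = [&](int f) {
    return is_varying[f] ? std::exp(ls[f]) : 1.0;
  };

  // cached linear predictor and pointwise log-likelihood
  std::vector<double> eta(N, 0.0), ll(N, 0.0);
  double phi = std::exp(lphi);
  for (int i = 0; i < N; ++i) {
    double e = alpha;
    for (int f = 0; f < F; ++f) e += scale_of(f) * z[f][levels(i, f)];
    eta[i] = e;
    ll[i] = ll_point(e, phi, logy[i], log1my[i]);
  }

  // proposal scales
  double s_alpha = 0.2, s_lphi = 0.2;
  std::vector<double> s_ls(F, 0.3), s_resc(F, 0.3);
  std::vector<std::vector<double>> s_z(F);
  for (int f = 0; f < F; ++f) s_z[f].assign(n_levels[f], 0.5);

  int n_varying = 0;
  for (int f = 0; f < F; ++f) if (is_varying[f]) ++n_varying;
  const int n_keep = iter - warmup;
  const int P = 1 + sum(n_levels) + n_varying + 1;
  NumericMatrix draws(n_keep, P);
  double acc_count = 0.0, prop_count = 0.0;

  std::vector<double> eta_prop(N), ll_prop(N);

  for (int t = 0; t < iter; ++t) {
    double gam = 0.5 / std::sqrt((double)(t + 1));
    bool adapting = t < warmup;

    // --- alpha (full-data random walk) ---
    {
      double a_new = alpha + s_alpha * norm_rand();
      double d = a_new - alpha, delta = 0.0;
      for (int i = 0; i < N; ++i) {
        ll_prop[i] = ll_point(eta[i] + d, phi, logy[i], log1my[i]);
        delta += ll_prop[i] - ll[i];
      }
      delta += -0.5 * (a_new * a_new - alpha * alpha);
      bool acc = std::log(unif_rand()) < delta;
      if (acc) {
        alpha = a_new;
        for (int i = 0; i < N; ++i) { eta[i] += d; ll[i] = ll_prop[i]; }
      }
      if (adapting) s_alpha *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_accept));
      prop_count += 1.0; acc_count += acc ? 1.0 : 0.0;
    }

    // --- level effects (subset random walks) ---
    for (int f = 0; f < F; ++f) {
      double sc = scale_of(f);
      for (int j = 0; j < n_levels[f]; ++j) {
        double z_new = z[f][j] + s_z[f][j] * norm_rand();
        double d = sc * (z_new - z[f][j]);
        double delta = -0.5 * (z_new * z_new - z[f][j] * z[f][j]);
        const std::vector<int>& obs = idx[f][j];
        for (size_t m = 0; m < obs.size(); ++m) {
          int i = obs[m];
          ll_prop[i] = ll_point(eta[i] + d, phi, logy[i], log1my[i]);
          delta += ll_prop[i] - ll[i];
        }
        bool acc = std::log(unif_rand()) < delta;
        if (acc) {
          z[f][j] = z_new;
          for (size_t m = 0; m < obs.size(); ++m) {
            int i = obs[m];
            eta[i] += d; ll[i] = ll_prop[i];
          }
        }
        if (adapting)
          s_z[f][j] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_accept));
        prop_count += 1.0; acc_count += acc ? 1.0 : 0.0;
      }
    }

    // --- log sigma per varying factor (full-data) ---
    for (int f = 0; f < F; ++f) {
      if (!is_varying[f]) continue;
      double ls_new = ls[f] + s_ls[f] * norm_rand();
      double sig_old = std::exp(ls[f]), sig_new = std::exp(ls_new);
      double dsig = sig_new - sig_old;
      double delta = 0.0;
      for (int i = 0; i < N; ++i) {
        eta_prop[i] = eta[i] + dsig * z[f][levels(i, f)];
        ll_prop[i] = ll_point(eta_prop[i], phi, logy[i], log1my[i]);
        delta += ll_prop[i] - ll[i];
      }
      // Exponential(rate) prior on sigma + log-scale Jacobian
      delta += -sigma_rate * dsig + (ls_new - ls[f]);
      bool acc = std::log(unif_rand()) < delta;
      if (acc) {
        ls[f] = ls_new;
        for (int i = 0; i < N; ++i) { eta[i] = eta_prop[i]; ll[i] = ll_prop[i]; }
      }
      if (adapting) s_ls[f] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_accept));
      prop_count += 1.0; acc_count += acc ? 1.0 : 0.0;
    }

    // --- recentering (exact Gibbs along the flat direction) ---
    // alpha -> alpha + d, z[f][.] -> z[f][.] - d / scale_f leaves every
    // eta_i unchanged, so the conditional of d involves only the Normal
    // priors and is Gaussian: precision 1 + J / scale^2, mean
    // (sum(z)/scale - alpha) / precision. This removes the translation
    // degeneracy between the grand mean and each factor's mean effect.
    for (int f = 0; f < F; ++f) {
      double sc = scale_of(f);
      if (sc <= 0.0) continue;
      double J = (double)n_levels[f], Sz = 0.0;
      for (int j = 0; j < n_levels[f]; ++j) Sz += z[f][j];
      double tau = 1.0 + J / (sc * sc);
      double mean_d = (Sz / sc - alpha) / tau;
      double d = mean_d + norm_rand() / std::sqrt(tau);
      alpha += d;
      for (int j = 0; j < n_levels[f]; ++j) z[f][j] -= d / sc;
    }

    // --- rescaling move per varying factor ---
    // sigma -> sigma e^l, z -> z e^{-l} leaves every effect sigma * z (and
    // hence the likelihood) unchanged; Metropolis along this ray explores
    // the sigma/z scale degeneracy of the non-centered parameterization.
    // Target in state (log sigma, z): -0.5 sum z^2 - rate * sigma +
    // log sigma; the deterministic map has Jacobian e^{-J l}.
    for (int f = 0; f < F; ++f) {
      if (!is_varying[f]) continue;
      double l = s_resc[f] * norm_rand();
      double sig = std::exp(ls[f]);
      double Sz2 = 0.0;
      for (int j = 0; j < n_levels[f]; ++j) Sz2 += z[f][j] * z[f][j];
      double J = (double)n_levels[f];
      double delta = -0.5 * Sz2 * (std::exp(-2.0 * l) - 1.0)
                     - sigma_rate * sig * (std::exp(l) - 1.0)
                     + l - J * l;
      bool acc = std::log(unif_rand()) < delta;
      if (acc) {
        ls[f] += l;
        double down = std::exp(-l);
        for (int j = 0; j < n_levels[f]; ++j) z[f][j] *= down;
      }
      if (adapting)
        s_resc[f] *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_accept));
    }

    // --- log phi (full-data) ---
    {
      double lphi_new = lphi + s_lphi * norm_rand();
      double phi_new = std::exp(lphi_new);
      double delta = 0.0;
      for (int i = 0; i < N; ++i) {
        ll_prop[i] = ll_point(eta[i], phi_new, logy[i], log1my[i]);
        delta += ll_prop[i] - ll[i];
      }
      // Gamma(shape, rate) prior on phi + Jacobian: shape * log phi - rate * phi
      delta += phi_shape * (lphi_new - lphi) - phi_rate * (phi_new - phi);
      bool acc = std::log(unif_rand()) < delta;
      if (acc) {
        lphi = lphi_new; phi = phi_new;
        for (int i = 0; i < N; ++i) ll[i] = ll_prop[i];
      }
      if (adapting) s_lphi *= std::exp(gam * ((acc ? 1.0 : 0.0) - target_accept));
      prop_count += 1.0; acc_count += acc ? 1.0 : 0.0;
    }

    // --- record ---
    if (t >= warmup) {
      int row = t - warmup, col = 0;
      draws(row, col++) = alpha;
      for (int f = 0; f < F; ++f) {
        double sc = scale_of(f);
        for (int j = 0; j < n_levels[f]; ++j) draws(row, col++) = sc * z[f][j];
      }
      for (int f = 0; f < F; ++f)
        if (is_varying[f]) draws(row, col++) = std::exp(ls[f]);
      draws(row, col++) = phi;
    }
  }

  return List::create(_["draws"] = draws,
                      _["accept_rate"] = acc_count / prop_count);
}
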