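#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// unnormalized log normal density (constants cancel in MH ratios)
static inline double ldnorm_u(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd);
}

// Robbins-Monro step size for proposal-scale adaptation (burn-in only)
static inline double rm_gamma(int iter) {
  return 1.0 / std::pow(1.0 + iter, 0.6);
}

// Metropolis-within-Gibbs sampler for the first-order decay model with a
// recalcitrant offset and latent true transport times:
//   y_i ~ N(Cdeg * exp(-k * t_i) + R, sy_i)
//   t_i ~ N(tau_i, stau_i)            (latent x-axis uncertainty)
//   Cdeg ~ U(0, cdeg_max), k ~ U(0, k_max), R ~ U(0, r_max)
// Component-wise Gaussian random-walk updates; per-parameter scales adapted
// toward `target` acceptance during burn-in, frozen afterwards. Uses R's RNG.
// [[Rcpp::export]]
List mcmc_decay_cpp(NumericVector tau, NumericVector stau,
                    NumericVector y, NumericVector sy,
                    int n_iter, int burn_in, int thin,
                    double target, double cdeg_max, double k_max,
                    double r_max, double cdeg_init, double k_init,
                    double r_init) {
  const int n = tau.size();
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, 3);

  double cdeg = cdeg_init, k = k_init, r = r_init;
  std::vector<double> t(n), E(n);
  for (int i = 0; i < n; ++i) { t[i] = tau[i]; E[i] = std::exp(-k * t[i]); }

  // proposal scales: 3 global parameters + n latent times
  double s_cdeg = 0.1 * (cdeg_init + r_init) + 1e-12;
  double s_k = 0.25, s_r = s_cdeg;
  std::vector<double> s_t(n);
  for (int i = 0; i < n; ++i) s_t[i] = std::max(stau[i], 1e-12);

  auto loglik_all = [&](double cd, double rr,
                        const std::vector<double>& Ev) {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += ldnorm_u(y[i], cd * Ev[i] + rr, sy[i]);
    return ll;
  };

  double ll = loglik_all(cdeg, r, E);
  long acc_post = 0, prop_post = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= burn_in;
    const double g = adapting ? rm_gamma(iter) : 0.0;

    // --- Cdeg ---
    {
      double p = cdeg + s_cdeg * R::norm_rand();
      int acc = 0;
      if (p > 0.0 && p < cdeg_max) {
        double llp = loglik_all(p, r, E);
        if (std::log(R::unif_rand()) < llp - ll) { cdeg = p; ll = llp; acc = 1; }
      }
      if (adapting) s_cdeg *= std::exp(g * (acc - target));
      else { acc_post += acc; ++prop_post; }
    }
    // --- k ---
    {
      double p = k + s_k * R::norm_rand();
      int acc = 0;
      if (p > 0.0 && p < k_max) {
        std::vector<double> Ep(n);
        for (int i = 0; i < n; ++i) Ep[i] = std::exp(-p * t[i]);
        double llp = loglik_all(cdeg, r, Ep);
        if (std::log(R::unif_rand()) < llp - ll) {
          k = p; ll = llp; E.swap(Ep); acc = 1;
        }
      }
      if (adapting) s_k *= std::exp(g * (acc - target));
      else { acc_post += acc; ++prop_post; }
    }
    // --- R ---
    {
      double p = r + s_r * R::norm_rand();
      int acc = 0;
      if (p >= 0.0 && p < r_max) {
        double llp = loglik_all(cdeg, p, E);
        if (std::log(R::unif_rand()) < llp - ll) { r = p; ll = llp; acc = 1; }
      }
      if (adapting) s_r *= std::exp(g * (acc - target));
      else { acc_post += acc; ++prop_post; }
    }
    // --- latent times (skipped where stau == 0: time is known exactly) ---
    for (int i = 0; i < n; ++i) {
      if (stau[i] <= 0.0) continue;
      double p = t[i] + s_t[i] * R::norm_rand();
      double Ei = std::exp(-k * p);
      double d = ldnorm_u(y[i], cdeg * Ei + r, sy[i])
               - ldnorm_u(y[i], cdeg * E[i] + r, sy[i])
               + ldnorm_u(p, tau[i], stau[i])
               - ldnorm_u(t[i], tau[i], stau[i]);
      int acc = 0;
      if (std::log(R::unif_rand()) < d) {
        // ll tracks the y-likelihood only; update its contribution
        ll += ldnorm_u(y[i], cdeg * Ei + r, sy[i])
            - ldnorm_u(y[i], cdeg * E[i] + r, sy[i]);
        t[i] = p; E[i] = Ei; acc = 1;
      }
      if (adapting) s_t[i] *= std::exp(g * (acc - target));
      else { acc_post += acc; ++prop_post; }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int row = (iter - burn_in) / thin - 1;
      draws(row, 0) = cdeg; draws(row, 1) = k; draws(row, 2) = r;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["acceptance_rate"] = prop_post > 0 ? (double)acc_post / prop_post : NA_REAL,
    _["scales"] = NumericVector::create(_["c_deg"] = s_cdeg, _["k"] = s_k,
                                        _["r"] = s_r));
}

// Partially collapsed Metropolis sampler for the dual-isotope
// three-endmember mixing model. The source fractions (f1, f2) live on the
// 2-simplex (f3 = 1 - f1 - f2) with a flat prior; the six endmember
// isotope values x_j have Normal(mu_j, sd_j) priors. Fraction updates use
// the endmember-MARGINALIZED likelihood (each tracer Normal around the
// mixture of prior means with variance s_obs^2 + sum_i f_i^2 sd_i^2),
// which is exact for Normal priors; the endmember values are then redrawn
// from their exact Gaussian conditional given the fractions (conjugate
// rank-1 update), so they remain sampled parameters while the fraction
// chain mixes at the marginal-posterior scale. Two adapted Metropolis
// blocks move the fractions: an isotropic simplex walk and an exchange
// move along the f1/f2 ridge (the slow direction when the two
// terrestrial endmembers are isotopically similar). Proposals leaving the
// simplex are rejected; scales tune toward `target` during burn-in and
// freeze afterwards. em_mu / em_sd are length 6:
// (d13C AL, ICD, marine, D14C AL, ICD, marine).
// [[Rcpp::export]]
List mcmc_mixing_cpp(double obs13, double s13, double obs14, double s14,
                     NumericVector em_mu, NumericVector em_sd,
                     int n_iter, int burn_in, int thin, double target,
                     double f1_init, double f2_init) {
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, 3);
  NumericMatrix em_draws(n_keep, 6);

  double f1 = f1_init, f2 = f2_init;

  // marginal log posterior over the fractions (endmembers integrated out)
  auto logpost = [&](double a, double b) {
    double f3 = 1.0 - a - b;
    double m13 = a * em_mu[0] + b * em_mu[1] + f3 * em_mu[2];
    double m14 = a * em_mu[3] + b * em_mu[4] + f3 * em_mu[5];
    double v13 = s13 * s13 + a * a * em_sd[0] * em_sd[0] +
                 b * b * em_sd[1] * em_sd[1] + f3 * f3 * em_sd[2] * em_sd[2];
    double v14 = s14 * s14 + a * a * em_sd[3] * em_sd[3] +
                 b * b * em_sd[4] * em_sd[4] + f3 * f3 * em_sd[5] * em_sd[5];
    return ldnorm_u(obs13, m13, std::sqrt(v13)) +
           ldnorm_u(obs14, m14, std::sqrt(v14));
  };

  // exact conjugate draw of one tracer's endmember triple given fractions:
  // prior x ~ N(m, diag(d2)), likelihood y ~ N(f.x, s2); posterior
  // covariance via Sherman-Morrison, sampled through its Cholesky factor
  auto draw_em = [&](const double* m, const double* sdv, double y,
                     double s2, const double* f, double* out) {
    double d2[3], Sf[3];
    for (int j = 0; j < 3; ++j) d2[j] = sdv[j] * sdv[j];
    double fDf = 0.0, fm = 0.0;
    for (int j = 0; j < 3; ++j) { fDf += f[j] * f[j] * d2[j]; fm += f[j] * m[j]; }
    double denom = s2 + fDf;
    // Sigma = D - (D f)(D f)^T / denom ; mu = m + D f (y - f.m) / denom
    for (int j = 0; j < 3; ++j) Sf[j] = d2[j] * f[j];
    double Sig[3][3], mu[3];
    for (int j = 0; j < 3; ++j) {
      mu[j] = m[j] + Sf[j] * (y - fm) / denom;
      for (int k = 0; k < 3; ++k)
        Sig[j][k] = (j == k ? d2[j] : 0.0) - Sf[j] * Sf[k] / denom;
    }
    // 3x3 Cholesky
    double L[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = 0; j < 3; ++j) {
      for (int k = 0; k <= j; ++k) {
        double s = Sig[j][k];
        for (int q = 0; q < k; ++q) s -= L[j][q] * L[k][q];
        L[j][k] = (j == k) ? std::sqrt(std::max(s, 0.0))
                           : (L[k][k] > 0 ? s / L[k][k] : 0.0);
      }
    }
    double z[3] = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
    for (int j = 0; j < 3; ++j) {
      out[j] = mu[j];
      for (int k = 0; k <= j; ++k) out[j] += L[j][k] * z[k];
    }
  };

  double lp = logpost(f1, f2);
  double s_f = 0.15, s_e = 0.3;
  long acc_post = 0, prop_post = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= burn_in;
    const double g = adapting ? rm_gamma(iter) : 0.0;

    // --- isotropic simplex walk ---
    {
      double p1 = f1 + s_f * R::norm_rand();
      double p2 = f2 + s_f * R::norm_rand();
      int acc = 0;
      if (p1 >= 0.0 && p2 >= 0.0 && p1 + p2 <= 1.0) {
        double lpp = logpost(p1, p2);
        if (std::log(R::unif_rand()) < lpp - lp) {
          f1 = p1; f2 = p2; lp = lpp; acc = 1;
        }
      }
      if (adapting) s_f *= std::exp(g * (acc - target));
      else { acc_post += acc; ++prop_post; }
    }
    // --- exchange move along the f1/f2 ridge (f3 fixed) ---
    {
      double d = s_e * R::norm_rand();
      double p1 = f1 + d, p2 = f2 - d;
      int acc = 0;
      if (p1 >= 0.0 && p2 >= 0.0 && p1 + p2 <= 1.0) {
        double lpp = logpost(p1, p2);
        if (std::log(R::unif_rand()) < lpp - lp) {
          f1 = p1; f2 = p2; lp = lpp; acc = 1;
        }
      }
      if (adapting) s_e *= std::exp(g * (acc - target));
      else { acc_post += acc; ++prop_post; }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int row = (iter - burn_in) / thin - 1;
      draws(row, 0) = f1; draws(row, 1) = f2; draws(row, 2) = 1.0 - f1 - f2;
      // endmember values: exact conditional draw given current fractions
      double f[3] = {f1, f2, 1.0 - f1 - f2};
      double m13v[3] = {em_mu[0], em_mu[1], em_mu[2]};
      double sd13v[3] = {em_sd[0], em_sd[1], em_sd[2]};
      double m14v[3] = {em_mu[3], em_mu[4], em_mu[5]};
      double sd14v[3] = {em_sd[3], em_sd[4], em_sd[5]};
      double x13[3], x14[3];
      draw_em(m13v, sd13v, obs13, s13 * s13, f, x13);
      draw_em(m14v, sd14v, obs14, s14 * s14, f, x14);
      for (int j = 0; j < 3; ++j) {
        em_draws(row, j) = x13[j];
        em_draws(row, 3 + j) = x14[j];
      }
    }
  }

  return List::create(
    _["draws"] = draws,
    _["em_draws"] = em_draws,
    _["acceptance_rate"] = prop_post > 0 ? (double)acc_post / prop_post : NA_REAL,
    _["scale"] = NumericVector::create(_["fractions"] = s_f,
                                       _["exchange"] = s_e));
}
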