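// Adaptive Metropolis-within-Gibbs sampler for the binomial-normal
// hierarchical meta-analysis model:
//   r_ij ~ Binomial(expit(mu_i +/- 0.5 * d_i), n_ij)
//   d_i  ~ N(delta, tau^2),  mu_i ~ N(mu0, mu_pv)
//   delta ~ N(0, delta_pv),  mu0 ~ N(0, mu0_pv)
// tau is sampled on an unconstrained transform x of the prior's native
// scale g(tau); log_prior_x includes the reparameterization Jacobian.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_expit(double x) {
  // log(1/(1+exp(-x))), stable for large |x|
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// prior types: 1 gamma on precision (p1 shape, p2 rate);
// 2/3/4 uniform (p1 lo, p2 hi) on log tau^2 / tau^2 / tau;
// 5/6 half-normal variance p1 on tau / tau^2; 7 DuMouchel (p1 = s0);
// 99 fixed at p1.
static double tau_from_x(int type, double p1, double p2, double x) {
  double t;
  switch (type) {
  case 1: return std::exp(-0.5 * x);                 // x = log precision
  case 2: t = sigmoid(x); return std::exp(0.5 * (p1 + (p2 - p1) * t));
  case 3: t = sigmoid(x); return std::sqrt(p1 + (p2 - p1) * t);
  case 4: t = sigmoid(x); return p1 + (p2 - p1) * t;
  case 5: return std::exp(x);                        // x = log tau
  case 6: return std::exp(0.5 * x);                  // x = log tau^2
  case 7: t = sigmoid(x); return p1 * (1.0 - t) / t; // t = shrinkage ratio
  default: return p1;
  }
}

static double log_prior_x(int type, double p1, double p2, double x) {
  double t, g;
  switch (type) {
  case 1: return p1 * x - p2 * std::exp(x);          // gamma(lp of log v)
  case 2: case 3: case 4: case 7:
    t = sigmoid(x);
    return std::log(t) + log1p(-t);                  // uniform + logit Jacobian
  case 5:
    g = std::exp(x);
    return -g * g / (2.0 * p1) + x;                  // half-normal on tau
  case 6:
    g = std::exp(x);
    return -g * g / (2.0 * p1) + x;                  // half-normal on tau^2
  default: return 0.0;
  }
}

// binomial log-likelihood of trial i at (mu, d)
static inline double trial_ll(int rT, int nT, int rC, int nC,
                              double mu, double d) {
  const double etaT = mu + 0.5 * d;
  const double etaC = mu - 0.5 * d;
  return rT * log_expit(etaT) + (nT - rT) * log_expit(-etaT) +
         rC * log_expit(etaC) + (nC - rC) * log_expit(-etaC);
}

static inline double dnorm_log(double x, double m, double sd) {
  const double z = (x - m) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// [[Rcpp::export]]
List bnhm_chain(IntegerVector rT, IntegerVector nT,
                IntegerVector rC, IntegerVector nC,
                int prior_type, double prior_p1, double prior_p2,
                double delta_pv, double mu_pv, double mu0_pv,
                int iter, int burnin, int thin,
                double delta0, double mu00, double x_tau0,
                NumericVector mu_init, NumericVector d_init,
                bool use_lik) {
  const int k = rT.size();
  const int n_par = 3 + 2 * k; // delta, tau, mu0, mu[1..k], d[1..k]
  const int n_save = (iter - burnin + thin - 1) / thin;
  NumericMatrix draws(n_save, n_par);

  double delta = delta0, mu0 = mu00, x_tau = x_tau0;
  double tau = tau_from_x(prior_type, prior_p1, prior_p2, x_tau);
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> d(d_init.begin(), d_init.end());

  // adaptive proposal log-scales: mu[1..k], d[1..k], x_tau
  std::vector<double> ls(2 * k + 1, std::log(0.5));
  std::vector<int> acc(2 * k + 1, 0);
  const int batch = 50;
  int batch_no = 0;

  RNGScope scope;

  for (int it = 0; it < iter; ++it) {
    const double tau2 = std::max(tau * tau, 1e-300);
    const double tau_sd = std::max(tau, 1e-150);

    // delta | d, tau  (normal-normal conjugate)
    {
      double prec = k / tau2 + 1.0 / delta_pv;
      double sum_d = 0.0;
      for (int i = 0; i < k; ++i) sum_d += d[i];
      double mean = (sum_d / tau2) / prec;
      delta = R::rnorm(mean, std::sqrt(1.0 / prec));
    }
    // mu0 | mu  (conjugate)
    {
      double prec = k / mu_pv + 1.0 / mu0_pv;
      double sum_mu = 0.0;
      for (int i = 0; i < k; ++i) sum_mu += mu[i];
      double mean = (sum_mu / mu_pv) / prec;
      mu0 = R::rnorm(mean, std::sqrt(1.0 / prec));
    }
    // mu_i and d_i random-walk Metropolis
    const double mu_sd = std::sqrt(mu_pv);
    for (int i = 0; i < k; ++i) {
      double prop = mu[i] + R::rnorm(0.0, std::exp(ls[i]));
      double cur_lp = dnorm_log(mu[i], mu0, mu_sd);
      double prop_lp = dnorm_log(prop, mu0, mu_sd);
      if (use_lik) {
        cur_lp += trial_ll(rT[i], nT[i], rC[i], nC[i], mu[i], d[i]);
        prop_lp += trial_ll(rT[i], nT[i], rC[i], nC[i], prop, d[i]);
      }
      if (std::log(R::unif_rand()) < prop_lp - cur_lp) {
        mu[i] = prop;
        ++acc[i];
      }
    }
    for (int i = 0; i < k; ++i) {
      double prop = d[i] + R::rnorm(0.0, std::exp(ls[k + i]));
      double cur_lp = dnorm_log(d[i], delta, tau_sd);
      double prop_lp = dnorm_log(prop, delta, tau_sd);
      if (use_lik) {
        cur_lp += trial_ll(rT[i], nT[i], rC[i], nC[i], mu[i], d[i]);
        prop_lp += trial_ll(rT[i], nT[i], rC[i], nC[i], mu[i], prop);
      }
      if (std::log(R::unif_rand()) < prop_lp - cur_lp) {
        d[i] = prop;
        ++acc[k + i];
      }
    }
    // tau via its unconstrained transform (skipped when fixed)
    if (prior_type != 99) {
      double prop_x = x_tau + R::rnorm(0.0, std::exp(ls[2 * k]));
      double prop_tau = tau_from_x(prior_type, prior_p1, prior_p2, prop_x);
      double prop_sd = std::max(prop_tau, 1e-150);
      double cur_lp = log_prior_x(prior_type, prior_p1, prior_p2, x_tau);
      double prop_lp = log_prior_x(prior_type, prior_p1, prior_p2, prop_x);
      for (int i = 0; i < k; ++i) {
        cur_lp += dnorm_log(d[i], delta, tau_sd);
        prop_lp += dnorm_log(d[i], delta, prop_sd);
      }
      if (std::isfinite(prop_lp) &&
          std::log(R::unif_rand()) < prop_lp - cur_lp) {
        x_tau = prop_x;
        tau = prop_tau;
        ++acc[2 * k];
      }
    }

    // Robbins-Monro adaptation of proposal scales, burn-in only
    if (it < burnin && (it + 1) % batch == 0) {
      ++batch_no;
      const double step = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
      for (size_t j = 0; j < ls.size(); ++j) {
        ls[j] += (acc[j] > 0.44 * batch) ? step : -step;
        acc[j] = 0;
      }
    }

    if (it >= burnin && (it - burnin) % thin == 0) {
      const int row = (it - burnin) / thin;
      draws(row, 0) = delta;
      draws(row, 1) = tau;
      draws(row, 2) = mu0;
      for (int i = 0; i < k; ++i) {
        draws(row, 3 + i) = mu[i];
        draws(row, 3 + k + i) = d[i];
      }
    }
  }

  return List::create(_["draws"] = draws);
}
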