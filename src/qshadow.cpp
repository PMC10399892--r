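#include <Rcpp.h>
using namespace Rcpp;

// log(1/(1+exp(-x))), stable over the full beta*dQ range
static inline double log_logistic(double x) {
  if (x < 0.0) return x - log1p(std::exp(x));
  return -log1p(std::exp(-x));
}

// Replay the asymmetric Q-learning recursion for one subject.
// choice: 0/1, outcome: coded -1/0/+1, block: reset marker (Q -> q0 on change).
// Returns total log likelihood of the observed choices under the softmax rule.
// [[Rcpp::export]]
double cpp_loglik(const IntegerVector& choice, const NumericVector& outcome,
                  const IntegerVector& block, double q0, double alpha_p,
                  double alpha_n, double beta) {
  const int T = choice.size();
  double q[2] = {q0, q0};
  int cur_block = T > 0 ? block[0] : 0;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (block[t] != cur_block) {
      cur_block = block[t];
      q[0] = q0; q[1] = q0;
    }
    const int c = choice[t];
    ll += log_logistic(beta * (q[c] - q[1 - c]));
    const double delta = outcome[t] - q[c];
    q[c] += (delta >= 0.0 ? alpha_p : alpha_n) * delta;
  }
  return ll;
}

// Same replay, exposing per-trial internals: pre-update Q values of both
// options, the chosen option's pre-update value, and the prediction error.
// [[Rcpp::export]]
NumericMatrix cpp_q_trajectory(const IntegerVector& choice,
                               const NumericVector& outcome,
                               const IntegerVector& block, double q0,
                               double alpha_p, double alpha_n, double beta) {
  const int T = choice.size();
  NumericMatrix out(T, 5);  // q0_pre, q1_pre, q_chosen, delta, p_choice
  double q[2] = {q0, q0};
  int cur_block = T > 0 ? block[0] : 0;
  for (int t = 0; t < T; ++t) {
    if (block[t] != cur_block) {
      cur_block = block[t];
      q[0] = q0; q[1] = q0;
    }
    const int c = choice[t];
    out(t, 0) = q[0];
    out(t, 1) = q[1];
    out(t, 2) = q[c];
    const double delta = outcome[t] - q[c];
    out(t, 3) = delta;
    out(t, 4) = std::exp(log_logistic(beta * (q[c] - q[1 - c])));
    q[c] += (delta >= 0.0 ? alpha_p : alpha_n) * delta;
  }
  return out;
}

// Simulate one softmax Q-learning agent on a schedule given as per-trial
// reinforcement probabilities for the two options. Only the chosen option's
// outcome is drawn (partial feedback) and only its Q is updated.
// r_hi is the reinforced outcome code (gain +1, loss -1, mixed +1),
// r_lo the alternative (gain/loss 0, mixed -1). Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_agent(const NumericVector& p0, const NumericVector& p1,
                                 const IntegerVector& block, double q0,
                                 double alpha_p, double alpha_n, double beta,
                                 double r_hi, double r_lo) {
  const int T = p0.size();
  NumericMatrix out(T, 4);  // choice, outcome, q_chosen (pre-update), delta
  double q[2] = {q0, q0};
  int cur_block = T > 0 ? block[0] : 0;
  for (int t = 0; t < T; ++t) {
    if (block[t] != cur_block) {
      cur_block = block[t];
      q[0] = q0; q[1] = q0;
    }
    const double p_left = std::exp(log_logistic(beta * (q[0] - q[1])));
    const int c = unif_rand() < p_left ? 0 : 1;
    const double p_rein = c == 0 ? p0[t] : p1[t];
    const double r = unif_rand() < p_rein ? r_hi : r_lo;
    out(t, 0) = c;
    out(t, 1) = r;
    out(t, 2) = q[c];
    const double delta = r - q[c];
    out(t, 3) = delta;
    q[c] += (delta >= 0.0 ? alpha_p : alpha_n) * delta;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical sampler
//
// Model (RL mode): for each subject i and transformed parameter k,
//   raw_{ik} ~ Normal(mu_k, sigma_k),  mu_k ~ Normal(0, mu_prior_sd),
//   sigma_k ~ half-Cauchy(0, sigma_prior_scale);
// natural-scale parameters via the probit transform
//   q0 = q0_lo + Phi(raw_q0) (q0_hi - q0_lo)      (free-Q0 variants only)
//   alpha_p = Phi(raw_ap)
//   alpha_n = Phi(raw_ap + raw_delta)             (asymmetric variants only)
//   beta = beta_hi * Phi(raw_beta)
// and the data term is cpp_loglik.
//
// Updates: componentwise adaptive random-walk Metropolis on each subject's
// raw parameters (likelihood cached per subject), conjugate Gibbs for each
// mu_k, log-scale adaptive Metropolis for each sigma_k.
//
// mode = 1 swaps the RL data term for y_ij ~ Normal(raw_i, 1) with a single
// parameter per subject; this Gaussian instance of the identical hierarchy
// is used to validate the sampler against numerical quadrature.
// ---------------------------------------------------------------------------

struct SubjData {
  std::vector<int> choice;
  std::vector<double> outcome;
  std::vector<int> block;
  std::vector<double> y;  // mode 1
};

static double subj_loglik(const SubjData& d, int mode, bool free_q0, bool asym,
                          double fixed_q0, double q0_lo, double q0_hi,
                          double beta_hi, const double* raw) {
  if (mode == 1) {
    double ll = 0.0;
    for (size_t j = 0; j < d.y.size(); ++j) ll += R::dnorm(d.y[j], raw[0], 1.0, 1);
    return ll;
  }
  int k = 0;
  double q0 = fixed_q0;
  if (free_q0) q0 = q0_lo + R::pnorm(raw[k++], 0.0, 1.0, 1, 0) * (q0_hi - q0_lo);
  const double raw_ap = raw[k++];
  const double alpha_p = R::pnorm(raw_ap, 0.0, 1.0, 1, 0);
  double alpha_n = alpha_p;
  if (asym) alpha_n = R::pnorm(raw_ap + raw[k++], 0.0, 1.0, 1, 0);
  const double beta = beta_hi * R::pnorm(raw[k], 0.0, 1.0, 1, 0);
  const int T = d.choice.size();
  double q[2] = {q0, q0};
  int cur_block = T > 0 ? d.block[0] : 0;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (d.block[t] != cur_block) {
      cur_block = d.block[t];
      q[0] = q0; q[1] = q0;
    }
    const int c = d.choice[t];
    ll += log_logistic(beta * (q[c] - q[1 - c]));
    const double delta = d.outcome[t] - q[c];
    q[c] += (delta >= 0.0 ? alpha_p : alpha_n) * delta;
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_sample_chain(const List& subjects, int mode, bool free_q0, bool asym,
                      double fixed_q0, double q0_lo, double q0_hi,
                      double beta_hi, int n_warmup, int n_keep,
                      double mu_prior_sd, double sigma_prior_scale) {
  const int n = subjects.size();
  const int K = mode == 1 ? 1 : (free_q0 ? 1 : 0) + 1 + (asym ? 1 : 0) + 1;

  std::vector<SubjData> data(n);
  for (int i = 0; i < n; ++i) {
    List s = subjects[i];
    if (mode == 1) {
      NumericVector y = s["y"];
      data[i].y.assign(y.begin(), y.end());
    } else {
      IntegerVector ch = s["choice"], bl = s["block"];
      NumericVector oc = s["outcome"];
      data[i].choice.assign(ch.begin(), ch.end());
      data[i].block.assign(bl.begin(), bl.end());
      data[i].outcome.assign(oc.begin(), oc.end());
    }
  }

  std::vector<double> mu(K, 0.0), sigma(K, 1.0);
  std::vector<std::vector<double>> raw(n, std::vector<double>(K));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) raw[i][k] = 0.5 * norm_rand();

  std::vector<double> ll(n);
  for (int i = 0; i < n; ++i)
    ll[i] = subj_loglik(data[i], mode, free_q0, asym, fixed_q0, q0_lo, q0_hi,
                        beta_hi, raw[i].data());

  std::vector<std::vector<double>> lsd(n, std::vector<double>(K, std::log(0.5)));
  std::vector<double> lsd_sigma(K, std::log(0.5));
  std::vector<double> lsd_trans(K, std::log(0.2)), lsd_scale(K, std::log(0.3));
  std::vector<double> lsd_pair(n, std::log(0.5));
  double lsd_pair_g = std::log(0.2);
  const double target = 0.44;

  NumericMatrix out_mu(n_keep, K), out_sigma(n_keep, K);
  NumericMatrix out_raw(n_keep, n * K), out_ll(n_keep, n);

  const int n_iter = n_warmup + n_keep;
  std::vector<double> prop(K);
  for (int iter = 0; iter < n_iter; ++iter) {
    const bool adapting = iter < n_warmup;
    const double gain = adapting ? 1.0 / std::pow(iter + 1.0, 0.6) : 0.0;

    // subject-level raw parameters
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) {
        std::copy(raw[i].begin(), raw[i].end(), prop.begin());
        prop[k] = raw[i][k] + std::exp(lsd[i][k]) * norm_rand();
        const double ll_new = subj_loglik(data[i], mode, free_q0, asym,
                                          fixed_q0, q0_lo, q0_hi, beta_hi,
                                          prop.data());
        const double d = ll_new - ll[i] +
          R::dnorm(prop[k], mu[k], sigma[k], 1) -
          R::dnorm(raw[i][k], mu[k], sigma[k], 1);
        const double acc = d >= 0.0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) {
          raw[i][k] = prop[k];
          ll[i] = ll_new;
        }
        if (adapting) lsd[i][k] += gain * (acc - target);
      }
    }

    // hyper means: conjugate Gibbs (Normal prior, Normal likelihood)
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += raw[i][k];
      const double prec = n / (sigma[k] * sigma[k]) +
                          1.0 / (mu_prior_sd * mu_prior_sd);
      const double mean = (s / (sigma[k] * sigma[k])) / prec;
      mu[k] = mean + norm_rand() / std::sqrt(prec);
    }

    // anti-correlated pair move on (alpha_p_raw, delta): shifting one up
    // and the other down leaves alpha_n nearly fixed, the soft direction
    // of the asymmetric likelihood.
    if (mode == 0 && asym) {
      const int ka = free_q0 ? 1 : 0;  // alpha_p_raw index
      const int kd = ka + 1;           // delta index
      for (int i = 0; i < n; ++i) {
        const double eps = std::exp(lsd_pair[i]) * norm_rand();
        std::copy(raw[i].begin(), raw[i].end(), prop.begin());
        prop[ka] += eps;
        prop[kd] -= eps;
        const double ll_new = subj_loglik(data[i], mode, free_q0, asym,
                                          fixed_q0, q0_lo, q0_hi, beta_hi,
                                          prop.data());
        const double d = ll_new - ll[i] +
          R::dnorm(prop[ka], mu[ka], sigma[ka], 1) -
          R::dnorm(raw[i][ka], mu[ka], sigma[ka], 1) +
          R::dnorm(prop[kd], mu[kd], sigma[kd], 1) -
          R::dnorm(raw[i][kd], mu[kd], sigma[kd], 1);
        const double acc = d >= 0.0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) {
          raw[i][ka] = prop[ka];
          raw[i][kd] = prop[kd];
          ll[i] = ll_new;
        }
        if (adapting) lsd_pair[i] += gain * (acc - target);
      }

      // matching group-level pair translation
      const double eps = std::exp(lsd_pair_g) * norm_rand();
      double d = R::dnorm(mu[ka] + eps, 0.0, mu_prior_sd, 1) -
                 R::dnorm(mu[ka], 0.0, mu_prior_sd, 1) +
                 R::dnorm(mu[kd] - eps, 0.0, mu_prior_sd, 1) -
                 R::dnorm(mu[kd], 0.0, mu_prior_sd, 1);
      std::vector<double> ll_new(n);
      for (int i = 0; i < n; ++i) {
        std::copy(raw[i].begin(), raw[i].end(), prop.begin());
        prop[ka] += eps;
        prop[kd] -= eps;
        ll_new[i] = subj_loglik(data[i], mode, free_q0, asym, fixed_q0,
                                q0_lo, q0_hi, beta_hi, prop.data());
        d += ll_new[i] - ll[i];
      }
      const double acc = d >= 0.0 ? 1.0 : std::exp(d);
      if (unif_rand() < acc) {
        mu[ka] += eps;
        mu[kd] -= eps;
        for (int i = 0; i < n; ++i) {
          raw[i][ka] += eps;
          raw[i][kd] -= eps;
          ll[i] = ll_new[i];
        }
      }
      if (adapting) lsd_pair_g += gain * (acc - target);
    }

    // group translation move: shift mu_k and every raw_ik together.
    // Subject prior terms are invariant; only the mu prior and the data
    // terms change. Breaks the random-walk funnel when sigma_k is small.
    for (int k = 0; k < K; ++k) {
      const double eps = std::exp(lsd_trans[k]) * norm_rand();
      double d = R::dnorm(mu[k] + eps, 0.0, mu_prior_sd, 1) -
                 R::dnorm(mu[k], 0.0, mu_prior_sd, 1);
      std::vector<double> ll_new(n);
      for (int i = 0; i < n; ++i) {
        std::copy(raw[i].begin(), raw[i].end(), prop.begin());
        prop[k] += eps;
        ll_new[i] = subj_loglik(data[i], mode, free_q0, asym, fixed_q0,
                                q0_lo, q0_hi, beta_hi, prop.data());
        d += ll_new[i] - ll[i];
      }
      const double acc = d >= 0.0 ? 1.0 : std::exp(d);
      if (unif_rand() < acc) {
        mu[k] += eps;
        for (int i = 0; i < n; ++i) {
          raw[i][k] += eps;
          ll[i] = ll_new[i];
        }
      }
      if (adapting) lsd_trans[k] += gain * (acc - target);
    }

    // group scale move: sigma_k -> c * sigma_k with subject offsets from
    // mu_k rescaled by c. The Normal prior terms cancel against the
    // Jacobian, leaving the half-Cauchy ratio, log c, and the data terms.
    for (int k = 0; k < K; ++k) {
      const double c = std::exp(std::exp(lsd_scale[k]) * norm_rand());
      const double s_new = sigma[k] * c;
      double d = std::log(c);
      d += -std::log1p((s_new / sigma_prior_scale) * (s_new / sigma_prior_scale));
      d -= -std::log1p((sigma[k] / sigma_prior_scale) * (sigma[k] / sigma_prior_scale));
      std::vector<double> ll_new(n), raw_new(n);
      for (int i = 0; i < n; ++i) {
        std::copy(raw[i].begin(), raw[i].end(), prop.begin());
        raw_new[i] = mu[k] + (raw[i][k] - mu[k]) * c;
        prop[k] = raw_new[i];
        ll_new[i] = subj_loglik(data[i], mode, free_q0, asym, fixed_q0,
                                q0_lo, q0_hi, beta_hi, prop.data());
        d += ll_new[i] - ll[i];
      }
      const double acc = d >= 0.0 ? 1.0 : std::exp(d);
      if (unif_rand() < acc) {
        sigma[k] = s_new;
        for (int i = 0; i < n; ++i) {
          raw[i][k] = raw_new[i];
          ll[i] = ll_new[i];
        }
      }
      if (adapting) lsd_scale[k] += gain * (acc - target);
    }

    // hyper sds: log-scale MH with half-Cauchy prior (+ Jacobian)
    for (int k = 0; k < K; ++k) {
      const double s_new = sigma[k] * std::exp(std::exp(lsd_sigma[k]) * norm_rand());
      double d = std::log(s_new) - std::log(sigma[k]);  // Jacobian
      d += -std::log1p((s_new / sigma_prior_scale) * (s_new / sigma_prior_scale));
      d -= -std::log1p((sigma[k] / sigma_prior_scale) * (sigma[k] / sigma_prior_scale));
      for (int i = 0; i < n; ++i)
        d += R::dnorm(raw[i][k], mu[k], s_new, 1) -
             R::dnorm(raw[i][k], mu[k], sigma[k], 1);
      const double acc = d >= 0.0 ? 1.0 : std::exp(d);
      if (unif_rand() < acc) sigma[k] = s_new;
      if (adapting) lsd_sigma[k] += gain * (acc - target);
    }

    if (!adapting) {
      const int r = iter - n_warmup;
      for (int k = 0; k < K; ++k) {
        out_mu(r, k) = mu[k];
        out_sigma(r, k) = sigma[k];
      }
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k) out_raw(r, i * K + k) = raw[i][k];
        out_ll(r, i) = ll[i];
      }
    }
  }

  return List::create(_["mu"] = out_mu, _["sigma"] = out_sigma,
                      _["raw"] = out_raw, _["loglik"] = out_ll,
                      _["n_params"] = K);
}
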