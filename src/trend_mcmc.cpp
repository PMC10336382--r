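// MCMC sampler for Brownian-motion trait evolution with partition-specific
// rates and group-specific trend parameters under hierarchical priors.
//
// Model, per branch b (child node c with parent p):
//   x_c ~ Normal(x_p + mu[group(b)] * t_b, sigma2[part(b)] * t_b)
// Priors: mu_g ~ N(0, s_mu^2) with s_mu fixed or s_mu ~ Exp(hyper_rate);
//         sigma2_r ~ Exp(lambda) with lambda fixed or lambda ~ Exp(1);
//         root value ~ N(root_mean, root_sd^2) unless fixed.
//
// Updates: Gibbs (conditional normal) for ancestral values and trends;
// Metropolis-Hastings on the log scale for rates and s_mu; conjugate
// Gamma draw for lambda. Proposal scales adapt during burn-in only.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List trend_mcmc_cpp(const IntegerVector parent,    // 1-based, 0 = root
                    const NumericVector blen,      // branch to parent
                    const IntegerVector trend_grp, // 0 = no trend, 1..G
                    const IntegerVector rate_grp,  // 1..R
                    const LogicalVector is_tip,
                    const NumericVector x_init,
                    const int G, const int R,
                    const double root_mean, const double root_sd,
                    const bool root_fixed,
                    const bool s_mu_free, const double s_mu_init,
                    const double s_mu_hyper_rate,
                    const bool lambda_free, const double lambda_init,
                    const NumericVector sigma2_init,
                    const bool rates_fixed,
                    const bool prior_only,
                    const int iterations, const int burnin, const int thin) {
  const int n = parent.size();
  RNGScope scope;

  // children lists (flattened)
  std::vector<int> child_count(n, 0);
  for (int i = 0; i < n; ++i)
    if (parent[i] > 0) child_count[parent[i] - 1]++;
  std::vector<int> child_start(n + 1, 0);
  for (int i = 0; i < n; ++i) child_start[i + 1] = child_start[i] + child_count[i];
  std::vector<int> children(child_start[n]);
  {
    std::vector<int> fill(n, 0);
    for (int i = 0; i < n; ++i)
      if (parent[i] > 0) {
        int p = parent[i] - 1;
        children[child_start[p] + fill[p]++] = i;
      }
  }
  int root = -1;
  for (int i = 0; i < n; ++i) if (parent[i] == 0) root = i;

  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> sigma2(sigma2_init.begin(), sigma2_init.end());
  std::vector<double> mu(G, 0.0);
  double s_mu = s_mu_init;
  double lambda = lambda_init;

  // adaptive proposal scales (log-scale steps)
  std::vector<double> step_rate(R, 0.5);
  double step_smu = 0.5;
  std::vector<int> acc_rate(R, 0), try_rate(R, 0);
  int acc_smu = 0, try_smu = 0;

  const int n_keep = (iterations - burnin) / thin;
  const int ncol = 1 + R + G + 2 + 1;  // logLik, rates, trends, s_mu, lambda, root
  NumericMatrix samples(n_keep, ncol);
  std::vector<double> node_sum(n, 0.0), node_sumsq(n, 0.0);
  int kept = 0;

  std::vector<double> ss(R), nb(R);         // per-rate-group residual stats
  std::vector<double> mu_num(G), mu_prec(G);

  for (int it = 0; it < iterations; ++it) {
    // ---- (i) Gibbs update of ancestral (internal + root) values ----
    if (!prior_only) {
      for (int i = 0; i < n; ++i) {
        if (is_tip[i]) continue;
        if (i == root && root_fixed) continue;
        double prec = 0.0, num = 0.0;
        if (parent[i] > 0) {
          int p = parent[i] - 1;
          double v = sigma2[rate_grp[i] - 1] * blen[i];
          double drift = (trend_grp[i] > 0 ? mu[trend_grp[i] - 1] : 0.0) * blen[i];
          prec += 1.0 / v;
          num += (x[p] + drift) / v;
        } else {
          double v0 = root_sd * root_sd;
          prec += 1.0 / v0;
          num += root_mean / v0;
        }
        for (int k = child_start[i]; k < child_start[i + 1]; ++k) {
          int c = children[k];
          double v = sigma2[rate_grp[c] - 1] * blen[c];
          double drift = (trend_grp[c] > 0 ? mu[trend_grp[c] - 1] : 0.0) * blen[c];
          prec += 1.0 / v;
          num += (x[c] - drift) / v;
        }
        x[i] = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      }
    }

    // ---- branch sweep: residual stats per rate group, trend stats ----
    std::fill(ss.begin(), ss.end(), 0.0);
    std::fill(nb.begin(), nb.end(), 0.0);
    std::fill(mu_num.begin(), mu_num.end(), 0.0);
    std::fill(mu_prec.begin(), mu_prec.end(), 0.0);
    double loglik = 0.0;
    if (!prior_only) {
      for (int i = 0; i < n; ++i) {
        if (parent[i] == 0) continue;
        int p = parent[i] - 1;
        int r = rate_grp[i] - 1;
        double t = blen[i];
        double d = x[i] - x[p];
        double drift = (trend_grp[i] > 0 ? mu[trend_grp[i] - 1] : 0.0) * t;
        double resid = d - drift;
        double v = sigma2[r] * t;
        ss[r] += resid * resid / t;
        nb[r] += 1.0;
        loglik += -0.5 * std::log(2.0 * M_PI * v) - resid * resid / (2.0 * v);
        if (trend_grp[i] > 0) {
          int g = trend_grp[i] - 1;
          mu_prec[g] += t / sigma2[r];
          mu_num[g] += d / sigma2[r];
        }
      }
    }

    // ---- (ii) MH update of each rate sigma2_r (log scale) ----
    for (int r = 0; r < R && !rates_fixed; ++r) {
      double s0 = sigma2[r];
      double s1 = s0 * std::exp(step_rate[r] * R::rnorm(0.0, 1.0));
      // conditional: -0.5 nb log s - ss/(2s); prior Exp(lambda); Jacobian log s
      double la = -0.5 * nb[r] * (std::log(s1) - std::log(s0))
                  - 0.5 * ss[r] * (1.0 / s1 - 1.0 / s0)
                  - lambda * (s1 - s0)
                  + (std::log(s1) - std::log(s0));
      try_rate[r]++;
      if (std::log(R::runif(0.0, 1.0)) < la) {
        sigma2[r] = s1;
        acc_rate[r]++;
      }
    }
    if (!prior_only) {
      // refresh trend stats with the accepted rates
      std::fill(mu_num.begin(), mu_num.end(), 0.0);
      std::fill(mu_prec.begin(), mu_prec.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        if (parent[i] == 0 || trend_grp[i] == 0) continue;
        int p = parent[i] - 1, g = trend_grp[i] - 1, r = rate_grp[i] - 1;
        mu_prec[g] += blen[i] / sigma2[r];
        mu_num[g] += (x[i] - x[p]) / sigma2[r];
      }
    }

    // ---- (iii) conjugate Gibbs for trends ----
    for (int g = 0; g < G; ++g) {
      double prec = mu_prec[g] + 1.0 / (s_mu * s_mu);
      double mean = mu_num[g] / prec;
      mu[g] = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
    }

    // ---- (iv) hyperparameters ----
    if (s_mu_free) {
      double s0 = s_mu;
      double s1 = s0 * std::exp(step_smu * R::rnorm(0.0, 1.0));
      double la = 0.0;
      for (int g = 0; g < G; ++g) {
        la += R::dnorm(mu[g], 0.0, s1, 1) - R::dnorm(mu[g], 0.0, s0, 1);
      }
      la += -s_mu_hyper_rate * (s1 - s0) + (std::log(s1) - std::log(s0));
      try_smu++;
      if (std::log(R::runif(0.0, 1.0)) < la) {
        s_mu = s1;
        acc_smu++;
      }
    }
    if (lambda_free) {
      double sum_s = 0.0;
      for (int r = 0; r < R; ++r) sum_s += sigma2[r];
      lambda = R::rgamma(1.0 + R, 1.0 / (1.0 + sum_s));
    }

    // ---- adapt proposals during burn-in ----
    if (it < burnin && (it + 1) % 50 == 0) {
      for (int r = 0; r < R; ++r) {
        double a = try_rate[r] ? (double)acc_rate[r] / try_rate[r] : 0.3;
        step_rate[r] *= std::exp(0.6 * (a - 0.3));
        step_rate[r] = std::min(std::max(step_rate[r], 1e-3), 10.0);
        acc_rate[r] = try_rate[r] = 0;
      }
      if (s_mu_free) {
        double a = try_smu ? (double)acc_smu / try_smu : 0.3;
        step_smu = std::min(std::max(step_smu * std::exp(0.6 * (a - 0.3)),
                                     1e-3), 10.0);
        acc_smu = try_smu = 0;
      }
    }

    // ---- record ----
    if (it >= burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      int j = 0;
      samples(kept, j++) = loglik;
      for (int r = 0; r < R; ++r) samples(kept, j++) = sigma2[r];
      for (int g = 0; g < G; ++g) samples(kept, j++) = mu[g];
      samples(kept, j++) = s_mu;
      samples(kept, j++) = lambda;
      samples(kept, j++) = x[root];
      for (int i = 0; i < n; ++i) {
        node_sum[i] += x[i];
        node_sumsq[i] += x[i] * x[i];
      }
      kept++;
    }
  }

  NumericVector nmean(n), nsd(n);
  for (int i = 0; i < n; ++i) {
    nmean[i] = node_sum[i] / std::max(kept, 1);
    double v = node_sumsq[i] / std::max(kept, 1) - nmean[i] * nmean[i];
    nsd[i] = std::sqrt(std::max(v, 0.0));
  }
  return List::create(_["samples"] = samples,
                      _["node_mean"] = nmean,
                      _["node_sd"] = nsd,
                      _["kept"] = kept);
}
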