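#include <Rcpp.h>
using namespace Rcpp;

// Gibbs samplers for whole-genome regression on a centered dosage matrix.
// Both use R's RNG so set.seed() upstream makes runs bit-reproducible.

static double rinvgauss(double mean, double shape) {
  // Michael-Schucany-Haas
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mean + mean * mean * y / (2.0 * shape) -
    mean / (2.0 * shape) * std::sqrt(4.0 * mean * shape * y + mean * mean * y * y);
  if (x <= 0.0) x = 1e-12;
  if (R::unif_rand() <= mean / (mean + x)) return x;
  return mean * mean / x;
}

static double var_vec(const std::vector<double>& g) {
  double s = 0.0, ss = 0.0;
  int n = g.size();
  for (int i = 0; i < n; i++) s += g[i];
  double m = s / n;
  for (int i = 0; i < n; i++) ss += (g[i] - m) * (g[i] - m);
  return ss / (n - 1);
}

// [[Rcpp::export]]
List bayesb_gibbs(NumericVector y, NumericMatrix Z,
                  int n_iter, int burn_in, int thin,
                  double df_slab = 5.0, double R2 = 0.5,
                  double pi_a = 2.0, double pi_b = 2.0) {
  int n = Z.nrow(), m = Z.ncol();
  std::vector<double> zsq(m);
  double msx = 0.0;
  for (int j = 0; j < m; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
    msx += s / n;
  }
  double vy = var_vec(as<std::vector<double>>(y));
  double pi0 = 0.5;
  // slab scale from the R2 heuristic: pi0 * MSx * E[slab var] = R2 * var(y)
  double S2 = R2 * vy * (df_slab - 2.0) / (df_slab * pi0 * msx);
  double df_e = 5.0;
  double Se2 = (1.0 - R2) * vy * (df_e + 2.0) / df_e;

  double mu = mean(y);
  double sigma_e2 = (1.0 - R2) * vy;
  double pi = pi0;
  std::vector<double> beta(m, 0.0), s2j(m, S2), e(n);
  std::vector<int> delta(m, 0);
  for (int i = 0; i < n; i++) e[i] = y[i] - mu;

  int n_keep = (n_iter - burn_in) / thin;
  NumericVector ch_se(n_keep), ch_vg(n_keep), ch_pi(n_keep);
  std::vector<double> beta_sum(m, 0.0);
  double mu_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; it++) {
    // intercept
    double se = 0.0;
    for (int i = 0; i < n; i++) { e[i] += mu; se += e[i]; }
    mu = se / n + R::norm_rand() * std::sqrt(sigma_e2 / n);
    for (int i = 0; i < n; i++) e[i] -= mu;

    int n_in = 0;
    for (int j = 0; j < m; j++) {
      const double* zj = &Z(0, j);
      if (delta[j] == 1) {
        for (int i = 0; i < n; i++) e[i] += zj[i] * beta[j];
      }
      double rhs = 0.0;
      for (int i = 0; i < n; i++) rhs += zj[i] * e[i];
      double v1 = s2j[j] * zsq[j] + sigma_e2;
      double log_ratio = 0.5 * std::log(sigma_e2 / v1) +
        rhs * rhs * s2j[j] / (2.0 * sigma_e2 * v1);
      double log_odds = std::log(pi / (1.0 - pi)) + log_ratio;
      double p1 = 1.0 / (1.0 + std::exp(-log_odds));
      if (R::unif_rand() < p1) {
        double C = zsq[j] + sigma_e2 / s2j[j];
        beta[j] = rhs / C + R::norm_rand() * std::sqrt(sigma_e2 / C);
        delta[j] = 1;
        n_in++;
        for (int i = 0; i < n; i++) e[i] -= zj[i] * beta[j];
        s2j[j] = (df_slab * S2 + beta[j] * beta[j]) / R::rchisq(df_slab + 1.0);
      } else {
        beta[j] = 0.0;
        delta[j] = 0;
        s2j[j] = df_slab * S2 / R::rchisq(df_slab);
      }
    }
    pi = R::rbeta(pi_a + n_in, pi_b + m - n_in);

    double sse = 0.0;
    for (int i = 0; i < n; i++) sse += e[i] * e[i];
    sigma_e2 = (sse + df_e * Se2) / R::rchisq(n + df_e);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      std::vector<double> g(n);
      for (int i = 0; i < n; i++) g[i] = y[i] - mu - e[i];
      ch_se[kept] = sigma_e2;
      ch_vg[kept] = var_vec(g);
      ch_pi[kept] = pi;
      mu_sum += mu;
      for (int j = 0; j < m; j++) beta_sum[j] += beta[j];
      kept++;
    }
  }
  NumericVector beta_mean(m);
  for (int j = 0; j < m; j++) beta_mean[j] = beta_sum[j] / kept;
  return List::create(_["beta"] = beta_mean, _["mu"] = mu_sum / kept,
                      _["chain_sigma_e2"] = ch_se, _["chain_var_g"] = ch_vg,
                      _["chain_pi"] = ch_pi);
}

// [[Rcpp::export]]
List blasso_gibbs(NumericVector y, NumericMatrix Z,
                  int n_iter, int burn_in, int thin, double R2 = 0.5,
                  double lambda_shape = 1.1) {
  int n = Z.nrow(), m = Z.ncol();
  std::vector<double> zsq(m);
  double msx = 0.0;
  for (int j = 0; j < m; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
    msx += s / n;
  }
  double vy = var_vec(as<std::vector<double>>(y));
  // Park-Casella: marginal Var(beta_j) = 2 sigma_e2 / lambda^2; match the
  // expected genetic variance to R2 * var(y) for the prior mode of lambda^2
  double lambda2_0 = 2.0 * msx * (1.0 - R2) / R2;
  double lambda_rate = (lambda_shape - 1.0) / lambda2_0;
  if (lambda_rate <= 0.0) lambda_rate = 1e-4;
  double df_e = 5.0;
  double Se2 = (1.0 - R2) * vy * (df_e + 2.0) / df_e;

  double mu = mean(y);
  double sigma_e2 = (1.0 - R2) * vy;
  double lambda2 = lambda2_0;
  std::vector<double> beta(m, 0.0), tau2(m, 1.0 / lambda2_0), e(n);
  for (int i = 0; i < n; i++) e[i] = y[i] - mu;

  int n_keep = (n_iter - burn_in) / thin;
  NumericVector ch_se(n_keep), ch_vg(n_keep), ch_l2(n_keep);
  std::vector<double> beta_sum(m, 0.0);
  double mu_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; it++) {
    double se = 0.0;
    for (int i = 0; i < n; i++) { e[i] += mu; se += e[i]; }
    mu = se / n + R::norm_rand() * std::sqrt(sigma_e2 / n);
    for (int i = 0; i < n; i++) e[i] -= mu;

    double sum_b2_tau = 0.0, sum_tau2 = 0.0;
    for (int j = 0; j < m; j++) {
      const double* zj = &Z(0, j);
      for (int i = 0; i < n; i++) e[i] += zj[i] * beta[j];
      double rhs = 0.0;
      for (int i = 0; i < n; i++) rhs += zj[i] * e[i];
      double C = zsq[j] + 1.0 / tau2[j];
      beta[j] = rhs / C + R::norm_rand() * std::sqrt(sigma_e2 / C);
      for (int i = 0; i < n; i++) e[i] -= zj[i] * beta[j];

      double b2 = beta[j] * beta[j];
      if (b2 < 1e-20) b2 = 1e-20;
      double inv_tau2 = rinvgauss(std::sqrt(lambda2 * sigma_e2 / b2), lambda2);
      tau2[j] = 1.0 / inv_tau2;
      sum_b2_tau += b2 * inv_tau2;
      sum_tau2 += tau2[j];
    }
    lambda2 = R::rgamma(m + lambda_shape, 1.0 / (sum_tau2 / 2.0 + lambda_rate));

    double sse = 0.0;
    for (int i = 0; i < n; i++) sse += e[i] * e[i];
    sigma_e2 = (sse + sum_b2_tau + df_e * Se2) / R::rchisq(n + m + df_e);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      std::vector<double> g(n);
      for (int i = 0; i < n; i++) g[i] = y[i] - mu - e[i];
      ch_se[kept] = sigma_e2;
      ch_vg[kept] = var_vec(g);
      ch_l2[kept] = lambda2;
      mu_sum += mu;
      for (int j = 0; j < m; j++) beta_sum[j] += beta[j];
      kept++;
    }
  }
  NumericVector beta_mean(m);
  for (int j = 0; j < m; j++) beta_mean[j] = beta_sum[j] / kept;
  return List::create(_["beta"] = beta_mean, _["mu"] = mu_sum / kept,
                      _["chain_sigma_e2"] = ch_se, _["chain_var_g"] = ch_vg,
                      _["chain_lambda2"] = ch_l2);
}
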