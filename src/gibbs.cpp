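// Gibbs samplers for whole-genome regression with ridge, double-exponential
// and spike-and-slab marker-effect priors. All draws use R's RNG so chains
// are reproducible from set.seed() on the R side.
#include <Rcpp.h>
using namespace Rcpp;

// Michael-Schucany-Haas inverse-Gaussian sampler
static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (!(x > 0.0) || !std::isfinite(x)) x = mu;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double sum_sq(const NumericVector& v) {
  double s = 0.0;
  for (int i = 0; i < v.size(); ++i) s += v[i] * v[i];
  return s;
}

// [[Rcpp::export]]
List gibbs_brr_cpp(NumericVector y, NumericMatrix Z, int n_iter, int burn_in,
                   int thin, double df0, double S0_b, double S0_e,
                   bool fix_var, double s2b_fix, double s2e_fix) {
  const int n = y.size(), m = Z.ncol();
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  NumericVector beta(m, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = fix_var ? s2e_fix : std::max(var(y) * 0.5, 1e-8);
  double s2b = fix_var ? s2b_fix : std::max(S0_b / (df0 + 2.0), 1e-10);

  NumericVector beta_mean(m, 0.0);
  double mu_mean = 0.0, s2b_mean = 0.0, s2e_mean = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double ebar = mean(e);
    double mu_new = mu + ebar + norm_rand() * std::sqrt(s2e / n);
    for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
    mu = mu_new;
    // marker effects; posterior means are Rao-Blackwellized (the
    // full-conditional mean is averaged instead of the draw)
    bool keep = (it >= burn_in) && ((it - burn_in) % thin == 0);
    double lambda = s2e / s2b;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double rhs = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      double C = xtx[j] + lambda;
      double bnew = rhs / C + norm_rand() * std::sqrt(s2e / C);
      if (keep) beta_mean[j] += rhs / C;
      double diff = beta[j] - bnew;
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += Z(i, j) * diff;
      beta[j] = bnew;
    }
    if (!fix_var) {
      s2b = (sum_sq(beta) + S0_b) / R::rchisq(df0 + m);
      s2e = (sum_sq(e) + S0_e) / R::rchisq(df0 + n);
    }
    if (keep) {
      ++kept;
      mu_mean += mu; s2b_mean += s2b; s2e_mean += s2e;
    }
  }
  for (int j = 0; j < m; ++j) beta_mean[j] /= kept;
  return List::create(_["mu"] = mu_mean / kept, _["beta"] = beta_mean,
                      _["sigma2_beta"] = s2b_mean / kept,
                      _["sigma2_e"] = s2e_mean / kept, _["n_kept"] = kept);
}

// [[Rcpp::export]]
List gibbs_bl_cpp(NumericVector y, NumericMatrix Z, int n_iter, int burn_in,
                  int thin, double df0, double S0_e, double shape0,
                  double rate0, double lambda2_init, bool fix_lambda,
                  bool fix_s2e, double s2e_fix) {
  const int n = y.size(), m = Z.ncol();
  const double TAU2_MAX = 1e8;
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  NumericVector beta(m, 0.0), tau2(m, 1.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = fix_s2e ? s2e_fix : std::max(var(y) * 0.5, 1e-8);
  double lambda2 = lambda2_init;

  NumericVector beta_mean(m, 0.0);
  double mu_mean = 0.0, s2e_mean = 0.0, lam2_mean = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    double ebar = mean(e);
    double mu_new = mu + ebar + norm_rand() * std::sqrt(s2e / n);
    for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
    mu = mu_new;
    bool keep = (it >= burn_in) && ((it - burn_in) % thin == 0);
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double rhs = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      double C = xtx[j] + 1.0 / tau2[j];
      double bnew = rhs / C + norm_rand() * std::sqrt(s2e / C);
      if (keep) beta_mean[j] += rhs / C;
      double diff = beta[j] - bnew;
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += Z(i, j) * diff;
      beta[j] = bnew;
    }
    // tau2 full conditional: 1/tau2 ~ InvGauss(sqrt(lambda2 s2e / beta^2), lambda2)
    double sum_tau2 = 0.0, sum_b2_tau = 0.0;
    for (int j = 0; j < m; ++j) {
      double b2 = beta[j] * beta[j];
      double inv;
      if (b2 < 1e-300) inv = 1.0 / TAU2_MAX;
      else {
        double mu_ig = std::sqrt(lambda2 * s2e / b2);
        if (mu_ig > 1e8) mu_ig = 1e8;
        inv = rinvgauss1(mu_ig, lambda2);
      }
      tau2[j] = 1.0 / inv;
      if (tau2[j] > TAU2_MAX) tau2[j] = TAU2_MAX;
      sum_tau2 += tau2[j];
      sum_b2_tau += b2 / tau2[j];
    }
    if (!fix_lambda)
      lambda2 = R::rgamma(shape0 + m, 1.0 / (rate0 + sum_tau2 / 2.0));
    if (!fix_s2e)
      s2e = (sum_sq(e) + sum_b2_tau + S0_e) / R::rchisq(df0 + n + m);
    if (keep) {
      ++kept;
      mu_mean += mu; s2e_mean += s2e; lam2_mean += lambda2;
    }
  }
  for (int j = 0; j < m; ++j) beta_mean[j] /= kept;
  return List::create(_["mu"] = mu_mean / kept, _["beta"] = beta_mean,
                      _["sigma2_e"] = s2e_mean / kept,
                      _["lambda2"] = lam2_mean / kept, _["n_kept"] = kept);
}

// [[Rcpp::export]]
List gibbs_bayesb_cpp(NumericVector y, NumericMatrix Z, int n_iter,
                      int burn_in, int thin, double df0, double S0_B,
                      double S0_e, double pi_a, double pi_b, double pi_fix) {
  const int n = y.size(), m = Z.ncol();
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  NumericVector alpha(m, 0.0), s2j(m), e(n);
  IntegerVector delta(m, 0);
  for (int j = 0; j < m; ++j) s2j[j] = std::max(S0_B / (df0 + 2.0), 1e-10);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = std::max(var(y) * 0.5, 1e-8);
  bool sample_pi = !(pi_fix > 0.0);
  double pi = sample_pi ? pi_a / (pi_a + pi_b) : pi_fix;

  NumericVector eff_mean(m, 0.0), pip(m, 0.0);
  double mu_mean = 0.0, s2e_mean = 0.0, pi_mean = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    double ebar = mean(e);
    double mu_new = mu + ebar + norm_rand() * std::sqrt(s2e / n);
    for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
    mu = mu_new;
    bool keep = (it >= burn_in) && ((it - burn_in) % thin == 0);
    int n_in = 0;
    double logit_pi = std::log(pi) - std::log1p(-pi);
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { delta[j] = 0; alpha[j] = 0.0; continue; }
      // rhs excludes marker j's current contribution
      double rhs = (delta[j] == 1) ? xtx[j] * alpha[j] : 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      double C = xtx[j] + s2e / s2j[j];
      double log_odds = logit_pi +
        0.5 * (std::log(s2e / s2j[j]) - std::log(C)) +
        0.5 * rhs * rhs / (s2e * C);
      double p_in = 1.0 / (1.0 + std::exp(-log_odds));
      if (keep) { eff_mean[j] += p_in * rhs / C; pip[j] += p_in; }
      int d_new = (unif_rand() < p_in) ? 1 : 0;
      double a_new = 0.0;
      if (d_new == 1)
        a_new = rhs / C + norm_rand() * std::sqrt(s2e / C);
      double old_contrib = (delta[j] == 1) ? alpha[j] : 0.0;
      double diff = old_contrib - a_new * d_new;
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += Z(i, j) * diff;
      delta[j] = d_new;
      alpha[j] = a_new;
      n_in += d_new;
      // marker-specific slab variance (prior draw when excluded)
      double ss = (d_new == 1) ? a_new * a_new : 0.0;
      s2j[j] = (ss + S0_B) / R::rchisq(df0 + d_new);
    }
    if (sample_pi)
      pi = R::rbeta(pi_a + n_in, pi_b + m - n_in);
    if (pi < 1e-6) pi = 1e-6;
    if (pi > 1.0 - 1e-6) pi = 1.0 - 1e-6;
    s2e = (sum_sq(e) + S0_e) / R::rchisq(df0 + n);
    if (keep) {
      ++kept;
      mu_mean += mu; s2e_mean += s2e; pi_mean += pi;
    }
  }
  for (int j = 0; j < m; ++j) { eff_mean[j] /= kept; pip[j] /= kept; }
  return List::create(_["mu"] = mu_mean / kept, _["beta"] = eff_mean,
                      _["pip"] = pip, _["pi"] = pi_mean / kept,
                      _["sigma2_e"] = s2e_mean / kept, _["n_kept"] = kept);
}
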