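// Gibbs samplers for whole-genome regression: Bayesian ridge regression,
// BayesC (spike-and-slab with unknown pi) and the Bayesian Lasso
// (scale-mixture-of-normals). Single-site updates with the residual vector
// maintained incrementally; all randomness flows through R's RNG so chains
// are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian sampler (Michael, Schucany & Haas 1976).
static double rinvgauss(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) *
      std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0 || !R_finite(x)) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Scaled inverse-chi-squared draw with prior "sum" S (posterior form
// (S + SS) / chisq(df)).
static double rscaled_inv_chisq(double df, double S) {
  double c = R::rchisq(df);
  if (c <= 0.0) c = 1e-12;
  return S / c;
}

// [[Rcpp::export]]
List wgr_gibbs_cpp(NumericVector y, NumericMatrix W, NumericVector w,
                   int model, double df_beta, double S_beta, double df_e,
                   double S_e, double pi0, double p0, double lasso_rate,
                   double lasso_scale, int n_iter, int burn_in, int thin,
                   double pi_fix, double fix_sigma_e2, double fix_sigma_b2,
                   bool keep_effects, bool random_order, bool verbose) {
  const int n = y.size();
  const int p = W.ncol();
  if (W.nrow() != n) stop("dimension mismatch between y and W");

  // weight transform: row i multiplied by w_i makes residuals homoscedastic
  std::vector<double> wy(n), wint(n);
  double sw2 = 0.0;
  for (int i = 0; i < n; ++i) {
    wy[i] = w[i] * y[i];
    wint[i] = w[i];
    sw2 += w[i] * w[i];
  }
  NumericMatrix Wt(n, p);
  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = w[i] * W(i, j);
      Wt(i, j) = v;
      s += v * v;
    }
    xx[j] = s;
  }

  const bool fix_e = fix_sigma_e2 > 0.0;
  const bool fix_b = fix_sigma_b2 > 0.0;

  // initial state
  double mu = 0.0;
  {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += wint[i] * wy[i];
    mu = s / sw2;
  }
  std::vector<double> g(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = wy[i] - wint[i] * mu;
  double sigma_e2 = fix_e ? fix_sigma_e2 : S_e / (df_e + 2.0);
  double sigma_b2 = fix_b ? fix_sigma_b2 : S_beta / (df_beta + 2.0);
  double pi = (pi_fix >= 0.0) ? pi_fix : pi0;
  double lambda2 = lasso_scale > 0.0 ? lasso_rate / lasso_scale : 1.0;
  std::vector<int> delta(p, 1);
  std::vector<double> tau2(p, 1.0);
  if (sigma_e2 <= 0.0) sigma_e2 = 1e-8;

  const int n_saved = (n_iter - burn_in) / thin;
  std::vector<double> g_sum(p, 0.0), incl_sum(p, 0.0);
  NumericVector mu_chain(n_saved), sb2_chain(n_saved), se2_chain(n_saved),
      pi_chain(n_saved), l2_chain(n_saved);
  NumericMatrix g_chain(keep_effects ? n_saved : 1,
                        keep_effects ? p : 1);
  double mu_sum = 0.0;
  int saved = 0;

  std::vector<int> order(p);
  for (int j = 0; j < p; ++j) order[j] = j;

  RNGScope scope;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // intercept (flat prior)
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += wint[i] * (e[i] + wint[i] * mu);
      double mean = s / sw2;
      double mu_new = mean + norm_rand() * std::sqrt(sigma_e2 / sw2);
      double dmu = mu - mu_new;
      for (int i = 0; i < n; ++i) e[i] += wint[i] * dmu;
      mu = mu_new;
    }

    if (random_order) {
      for (int j = p - 1; j > 0; --j) {
        int k = (int)std::floor(unif_rand() * (j + 1));
        std::swap(order[j], order[k]);
      }
    }

    int m_in = p;
    double sum_g2_in = 0.0, sum_b2_over_tau = 0.0;
    if (model == 1) m_in = 0;

    for (int jj = 0; jj < p; ++jj) {
      const int j = order[jj];
      const double *col = &Wt(0, j);
      const double gj = g[j];
      // r = col' residual-without-j, computed without restoring e
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += col[i] * e[i];
      const double r = dot + xx[j] * gj;
      double gnew = 0.0;

      if (model == 0) { // BRR
        double q = xx[j] / sigma_e2 + 1.0 / sigma_b2;
        gnew = r / (sigma_e2 * q) + norm_rand() / std::sqrt(q);
        sum_g2_in += gnew * gnew;
      } else if (model == 1) { // BayesC
        double q = xx[j] / sigma_e2 + 1.0 / sigma_b2;
        double logbf = -0.5 * std::log(sigma_b2 * q) +
          r * r / (2.0 * sigma_e2 * sigma_e2 * q);
        double logodds = std::log(pi) - std::log1p(-pi) + logbf;
        int din;
        if (pi >= 1.0) din = 1;
        else if (pi <= 0.0) din = 0;
        else {
          double pr = 1.0 / (1.0 + std::exp(-logodds));
          din = (unif_rand() < pr) ? 1 : 0;
        }
        delta[j] = din;
        if (din) {
          gnew = r / (sigma_e2 * q) + norm_rand() / std::sqrt(q);
          sum_g2_in += gnew * gnew;
          ++m_in;
        }
      } else { // Bayesian Lasso
        double q = xx[j] / sigma_e2 + 1.0 / (tau2[j] * sigma_e2);
        gnew = r / (sigma_e2 * q) + norm_rand() / std::sqrt(q);
        double b2 = gnew * gnew;
        if (b2 < 1e-14) b2 = 1e-14;
        double mu_ig = std::sqrt(lambda2 * sigma_e2 / b2);
        double itau = rinvgauss(mu_ig, lambda2);
        tau2[j] = 1.0 / itau;
        sum_b2_over_tau += b2 / tau2[j];
      }

      const double d = gj - gnew;
      if (d != 0.0)
        for (int i = 0; i < n; ++i) e[i] += col[i] * d;
      g[j] = gnew;
    }

    // marker-effect variance / lasso rate
    if (model == 0 && !fix_b) {
      sigma_b2 = rscaled_inv_chisq(df_beta + p, S_beta + sum_g2_in);
    } else if (model == 1) {
      if (!fix_b)
        sigma_b2 = rscaled_inv_chisq(df_beta + m_in, S_beta + sum_g2_in);
      if (pi_fix < 0.0) {
        double a = p0 * pi0 + m_in;
        double b = p0 * (1.0 - pi0) + (p - m_in);
        pi = R::rbeta(a, b);
        if (pi < 1e-12) pi = 1e-12;
        if (pi > 1.0 - 1e-12) pi = 1.0 - 1e-12;
      }
    } else if (model == 2) {
      double sum_tau2 = 0.0;
      for (int j = 0; j < p; ++j) sum_tau2 += tau2[j];
      lambda2 = R::rgamma(lasso_rate + p,
                          1.0 / (lasso_scale + 0.5 * sum_tau2));
    }

    // residual variance
    if (!fix_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (model == 2) {
        sigma_e2 = rscaled_inv_chisq(df_e + n + p,
                                     S_e + sse + sum_b2_over_tau);
      } else {
        sigma_e2 = rscaled_inv_chisq(df_e + n, S_e + sse);
      }
    }

    if (iter > burn_in && ((iter - burn_in) % thin == 0) && saved < n_saved) {
      mu_sum += mu;
      mu_chain[saved] = mu;
      sb2_chain[saved] = sigma_b2;
      se2_chain[saved] = sigma_e2;
      pi_chain[saved] = pi;
      l2_chain[saved] = lambda2;
      for (int j = 0; j < p; ++j) {
        g_sum[j] += g[j];
        incl_sum[j] += delta[j];
        if (keep_effects) g_chain(saved, j) = g[j];
      }
      ++saved;
    }
    if (verbose && iter % 5000 == 0)
      Rcpp::Rcout << "iteration " << iter << "/" << n_iter << "\n";
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector g_mean(p), incl(p);
  for (int j = 0; j < p; ++j) {
    g_mean[j] = g_sum[j] / saved;
    incl[j] = incl_sum[j] / saved;
  }
  List out = List::create(
      _["mu_mean"] = mu_sum / saved, _["g_mean"] = g_mean,
      _["inclusion_prob"] = incl, _["mu_chain"] = mu_chain,
      _["sigma_b2_chain"] = sb2_chain, _["sigma_e2_chain"] = se2_chain,
      _["pi_chain"] = pi_chain, _["lambda2_chain"] = l2_chain);
  if (keep_effects) out["g_chain"] = g_chain;
  return out;
}
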