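// Gibbs sampler for the single-trait pedigree animal model
//   y = X beta + Z a + e,  a ~ N(0, A sigma_a2),  e ~ N(0, I sigma_e2),
// with flat priors on beta and scaled inverse-chi-squared priors on the
// variances. Fixed effects and additive values are updated one at a time;
// the additive full conditionals use the sparse inverse of A (CSR arrays
// built in R from the pedigree). Each animal carries at most one record.

#include <Rcpp.h>
using namespace Rcpp;

static double rscaled_inv_chisq(double df, double S) {
  double c = R::rchisq(df);
  if (c <= 0.0) c = 1e-12;
  return S / c;
}

// [[Rcpp::export]]
List animal_gibbs_cpp(NumericVector y, NumericMatrix X,
                      IntegerVector rec_animal, IntegerVector ai_ptr,
                      IntegerVector ai_idx, NumericVector ai_val, int n_anim,
                      double df_a, double S_a, double df_e, double S_e,
                      int n_iter, int burn_in, int thin,
                      double fix_sigma_a2, double fix_sigma_e2,
                      bool verbose) {
  const int n = y.size();
  const int f = X.ncol();
  if (X.nrow() != n || rec_animal.size() != n)
    stop("design dimensions disagree");

  // record index per animal (-1 = no record); one record per animal
  std::vector<int> rec_of(n_anim, -1);
  for (int i = 0; i < n; ++i) {
    int a = rec_animal[i];
    if (a < 0 || a >= n_anim) stop("record animal index out of range");
    if (rec_of[a] != -1) stop("animal with more than one record");
    rec_of[a] = i;
  }

  // sparse column view of X (contemporary-group dummies are mostly zero)
  std::vector<double> xx(f);
  std::vector<std::vector<int> > xidx(f);
  std::vector<std::vector<double> > xval(f);
  for (int k = 0; k < f; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = X(i, k);
      if (v != 0.0) {
        xidx[k].push_back(i);
        xval[k].push_back(v);
        s += v * v;
      }
    }
    if (s <= 0.0) stop("zero fixed-effect column (estimability)");
    xx[k] = s;
  }
  // diagonal of A-inverse, cached
  std::vector<double> adiag(n_anim, 0.0);
  for (int a = 0; a < n_anim; ++a) {
    for (int kk = ai_ptr[a]; kk < ai_ptr[a + 1]; ++kk)
      if (ai_idx[kk] == a) adiag[a] = ai_val[kk];
    if (adiag[a] <= 0.0) stop("invalid A-inverse diagonal");
  }

  std::vector<double> beta(f, 0.0), a(n_anim, 0.0), e(y.begin(), y.end());
  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy /= (n - 1);
  const bool fix_a = fix_sigma_a2 > 0.0, fix_e = fix_sigma_e2 > 0.0;
  double sigma_a2 = fix_a ? fix_sigma_a2 : 0.5 * vy;
  double sigma_e2 = fix_e ? fix_sigma_e2 : 0.5 * vy;

  const int n_saved = (n_iter - burn_in) / thin;
  NumericVector sa2_chain(n_saved), se2_chain(n_saved);
  std::vector<double> beta_sum(f, 0.0), a_sum(n_anim, 0.0),
      a_sum2(n_anim, 0.0);
  int saved = 0;

  RNGScope scope;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // fixed effects, flat prior
    for (int k = 0; k < f; ++k) {
      const double bk = beta[k];
      const std::vector<int> &idx = xidx[k];
      const std::vector<double> &val = xval[k];
      const int m = (int)idx.size();
      double r = 0.0;
      for (int t = 0; t < m; ++t) r += val[t] * (e[idx[t]] + val[t] * bk);
      double mean = r / xx[k];
      double bnew = mean + norm_rand() * std::sqrt(sigma_e2 / xx[k]);
      double d = bk - bnew;
      for (int t = 0; t < m; ++t) e[idx[t]] += val[t] * d;
      beta[k] = bnew;
    }

    // additive values
    const double la = 1.0 / sigma_a2, le = 1.0 / sigma_e2;
    for (int an = 0; an < n_anim; ++an) {
      int rec = rec_of[an];
      double aold = a[an];
      double off = 0.0;
      for (int kk = ai_ptr[an]; kk < ai_ptr[an + 1]; ++kk) {
        int j = ai_idx[kk];
        if (j != an) off += ai_val[kk] * a[j];
      }
      double q = adiag[an] * la;
      double r = -off * la;
      if (rec >= 0) {
        q += le;
        r += (e[rec] + aold) * le;
      }
      double anew = r / q + norm_rand() / std::sqrt(q);
      if (rec >= 0) e[rec] += aold - anew;
      a[an] = anew;
    }

    // variance components
    double quad = 0.0;
    for (int an = 0; an < n_anim; ++an) {
      double s = 0.0;
      for (int kk = ai_ptr[an]; kk < ai_ptr[an + 1]; ++kk)
        s += ai_val[kk] * a[ai_idx[kk]];
      quad += a[an] * s;
    }
    if (!fix_a) sigma_a2 = rscaled_inv_chisq(df_a + n_anim, S_a + quad);
    if (!fix_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = rscaled_inv_chisq(df_e + n, S_e + sse);
    }

    // Interweaving (ASIS) move: re-draw sigma_a in the ancillary
    // parameterisation a = sigma_a * a_tilde, which rescales all additive
    // values jointly and breaks the strong a--sigma_a2 posterior coupling
    // that makes the sufficient-parameterisation update mix slowly.
    if (!fix_a) {
      double sa = std::sqrt(sigma_a2);
      double ssq = 0.0, sp = 0.0;
      for (int an = 0; an < n_anim; ++an) {
        int rec = rec_of[an];
        if (rec < 0) continue;
        double atil = a[an] / sa;
        ssq += atil * atil;
        sp += atil * (e[rec] + a[an]);
      }
      if (ssq > 0.0) {
        double m = sp / ssq, v = sigma_e2 / ssq;
        double prop = m + norm_rand() * std::sqrt(v);
        if (prop != 0.0) {
          // log prior of sigma_a2 plus the |d sigma_a2 / d sigma_a| Jacobian
          double lp_prop = -(0.5 * df_a + 1.0) * std::log(prop * prop) -
                           S_a / (2.0 * prop * prop) + std::log(std::fabs(prop));
          double lp_cur = -(0.5 * df_a + 1.0) * std::log(sigma_a2) -
                          S_a / (2.0 * sigma_a2) + std::log(sa);
          if (std::log(unif_rand()) < lp_prop - lp_cur) {
            double ratio = prop / sa;
            for (int an = 0; an < n_anim; ++an) {
              double aold = a[an];
              a[an] = aold * ratio;
              int rec = rec_of[an];
              if (rec >= 0) e[rec] += aold - a[an];
            }
            sigma_a2 = prop * prop;
          }
        }
      }
    }

    if (iter > burn_in && ((iter - burn_in) % thin == 0) && saved < n_saved) {
      sa2_chain[saved] = sigma_a2;
      se2_chain[saved] = sigma_e2;
      for (int k = 0; k < f; ++k) beta_sum[k] += beta[k];
      for (int an = 0; an < n_anim; ++an) {
        a_sum[an] += a[an];
        a_sum2[an] += a[an] * a[an];
      }
      ++saved;
    }
    if (verbose && iter % 5000 == 0)
      Rcpp::Rcout << "iteration " << iter << "/" << n_iter << "\n";
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector beta_mean(f), a_mean(n_anim), a_var(n_anim);
  for (int k = 0; k < f; ++k) beta_mean[k] = beta_sum[k] / saved;
  for (int an = 0; an < n_anim; ++an) {
    double m = a_sum[an] / saved;
    a_mean[an] = m;
    double v = a_sum2[an] / saved - m * m;
    a_var[an] = v > 0.0 ? v * saved / std::max(1, saved - 1) : 0.0;
  }
  return List::create(_["beta_mean"] = beta_mean, _["a_mean"] = a_mean,
                      _["a_var"] = a_var, _["sigma_a2_chain"] = sa2_chain,
                      _["sigma_e2_chain"] = se2_chain);
}
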