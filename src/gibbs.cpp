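#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for Bayesian whole-genome regression with
// correlated Gaussian random effects sampled in the eigenbasis of their
// covariance kernels.
//
//   y = 1*mu + X m + sum_k U_k alpha_k + e,   e ~ N(0, sigma2_e I)
//   alpha_kj ~ N(0, sigma2_k * lambda_kj)     (kernel effect, eigenbasis)
//   m_j prior by method: 0 = BRR (common variance), 1 = BayesA (per-marker
//   scaled-inv-chi2 variances), 2 = BayesB (spike at 0 with prob pi_zero +
//   per-marker slab), 3 = BayesCpi (spike + common slab, pi sampled).
//
// Variance components have scaled-inverse-chi-square priors (df, S).
// Uses R's RNG so set.seed() gives bit-identical chains.

static inline double rinvchisq(double df, double scale_sum) {
  // draw from scaled-inv-chi2: scale_sum / chi2_df
  return scale_sum / R::rchisq(df);
}

// [[Rcpp::export]]
List gibbs_wgr(NumericVector y, NumericMatrix X,
               List kernelU, List kernelLambda,
               int method, int niter, int burnin, int thin,
               double df_m, double S_m, double df_e, double S_e,
               NumericVector df_k, NumericVector S_k,
               double pi_zero, bool sample_pi,
               double pi_beta_a, double pi_beta_b,
               bool fix_sigma_snp, double sigma_snp_value,
               bool fix_sigma_e, double sigma_e_value,
               bool prior_only) {
  const int n = y.size();
  const int p = X.ncol();
  const int nk = kernelU.size();
  const int nret = (niter - burnin) / thin;
  if (nret <= 0) stop("no retained draws: check niter/burnin/thin");

  // precompute marker squared norms; raw column pointers for the hot loops
  const double *Xp = X.begin();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    const double *xj = Xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  std::vector<NumericMatrix> U(nk);
  std::vector<NumericVector> lam(nk);
  std::vector<int> npos(nk, 0);
  for (int k = 0; k < nk; ++k) {
    U[k] = as<NumericMatrix>(kernelU[k]);
    lam[k] = as<NumericVector>(kernelLambda[k]);
    for (int j = 0; j < n; ++j) if (lam[k][j] > 1e-10) npos[k]++;
  }

  // state
  double mu = 0.0;
  std::vector<double> m(p, 0.0);
  std::vector<int> delta(p, 1);
  std::vector<double> s2j(p, S_m * df_m / std::max(df_m - 2.0, 0.5)); // per-marker var (BayesA/B)
  double s2snp = fix_sigma_snp ? sigma_snp_value
                               : S_m * df_m / std::max(df_m - 2.0, 0.5);
  double piz = pi_zero;
  std::vector<std::vector<double>> alpha(nk, std::vector<double>(n, 0.0));
  std::vector<double> s2k(nk);
  for (int k = 0; k < nk; ++k) s2k[k] = S_k[k] * df_k[k] / std::max(df_k[k] - 2.0, 0.5);
  double s2e = fix_sigma_e ? sigma_e_value : S_e * df_e / std::max(df_e - 2.0, 0.5);

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  // storage
  NumericVector dr_s2e(nret), dr_dev(nret), dr_pi(nret), dr_mu(nret);
  NumericMatrix dr_s2k(nret, nk);
  const bool per_marker_var = (method == 1 || method == 2);
  NumericMatrix dr_snpvar(nret, per_marker_var ? p : 1);
  std::vector<double> m_sum(p, 0.0), m_sumsq(p, 0.0);
  std::vector<std::vector<double>> a_sum(nk, std::vector<double>(n, 0.0));
  std::vector<double> incl_sum(p, 0.0);
  double mu_sum = 0.0;

  int stored = 0;
  for (int it = 0; it < niter; ++it) {
    // --- mu (flat prior)
    if (!prior_only) {
      double rbar = 0.0;
      for (int i = 0; i < n; ++i) rbar += r[i];
      double mu_new = R::rnorm((rbar + n * mu) / n, std::sqrt(s2e / n));
      double d = mu_new - mu;
      for (int i = 0; i < n; ++i) r[i] -= d;
      mu = mu_new;
    }

    // --- marker effects
    int nincl = 0;
    double msq_incl = 0.0, msq_all = 0.0;
    for (int j = 0; j < p; ++j) {
      double v = (method == 1 || method == 2) ? s2j[j] : s2snp;
      double mold = m[j];
      if (prior_only) {
        int dj = 1;
        if (method == 2 || method == 3) dj = (unif_rand() < piz) ? 0 : 1;
        delta[j] = dj;
        m[j] = dj ? R::rnorm(0.0, std::sqrt(v)) : 0.0;
      } else if (xtx[j] <= 0.0) {
        m[j] = 0.0; delta[j] = 0;
      } else {
        const double *xj = Xp + (size_t)j * n;
        double rhs = mold * xtx[j];
        for (int i = 0; i < n; ++i) rhs += xj[i] * r[i];
        bool include = true;
        if (method == 2 || method == 3) {
          // spike-and-slab: marginal likelihood ratio for inclusion
          double Ctil = xtx[j] * v + s2e;
          double logodds = std::log((1.0 - piz) / piz)
            + 0.5 * std::log(s2e / Ctil)
            + 0.5 * rhs * rhs * v / (s2e * Ctil);
          if (logodds > 35.0) logodds = 35.0;
          if (logodds < -35.0) logodds = -35.0;
          include = unif_rand() < 1.0 / (1.0 + std::exp(-logodds));
        }
        if (include) {
          double C = xtx[j] + s2e / v;
          m[j] = R::rnorm(rhs / C, std::sqrt(s2e / C));
          delta[j] = 1;
        } else {
          m[j] = 0.0;
          delta[j] = 0;
        }
        const double *xj2 = Xp + (size_t)j * n;
        double d = m[j] - mold;
        if (d != 0.0) for (int i = 0; i < n; ++i) r[i] -= xj2[i] * d;
      }
      if (delta[j]) { nincl++; msq_incl += m[j] * m[j]; }
      msq_all += m[j] * m[j];
      // per-marker variances (BayesA always; BayesB refreshes excluded
      // markers from the prior)
      if (method == 1) {
        s2j[j] = rinvchisq(df_m + 1.0, S_m * df_m + m[j] * m[j]);
      } else if (method == 2) {
        s2j[j] = delta[j] ? rinvchisq(df_m + 1.0, S_m * df_m + m[j] * m[j])
                          : rinvchisq(df_m, S_m * df_m);
      }
    }
    if (p > 0 && !fix_sigma_snp) {
      if (method == 0) s2snp = rinvchisq(df_m + p, S_m * df_m + msq_all);
      else if (method == 3) s2snp = rinvchisq(df_m + nincl, S_m * df_m + msq_incl);
    }
    if (method == 3 && sample_pi && p > 0) {
      piz = R::rbeta(pi_beta_a + (p - nincl), pi_beta_b + nincl);
      if (piz < 1e-8) piz = 1e-8;
      if (piz > 1.0 - 1e-8) piz = 1.0 - 1e-8;
    }

    // --- kernel effects in eigenbasis
    for (int k = 0; k < nk; ++k) {
      double asq = 0.0;
      for (int j = 0; j < n; ++j) {
        double lj = lam[k][j];
        if (lj <= 1e-10) { alpha[k][j] = 0.0; continue; }
        double aold = alpha[k][j];
        if (prior_only) {
          alpha[k][j] = R::rnorm(0.0, std::sqrt(s2k[k] * lj));
        } else {
          const double *uj = U[k].begin() + (size_t)j * n;
          double rhs = aold;
          for (int i = 0; i < n; ++i) rhs += uj[i] * r[i];
          double C = 1.0 + s2e / (s2k[k] * lj);
          alpha[k][j] = R::rnorm(rhs / C, std::sqrt(s2e / C));
          double d = alpha[k][j] - aold;
          if (d != 0.0) for (int i = 0; i < n; ++i) r[i] -= uj[i] * d;
        }
        asq += alpha[k][j] * alpha[k][j] / lj;
      }
      s2k[k] = rinvchisq(df_k[k] + npos[k], S_k[k] * df_k[k] + asq);
      if (!std::isfinite(s2k[k])) stop("divergent kernel variance draw");
    }

    // --- residual variance and deviance
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    if (!fix_sigma_e) {
      s2e = prior_only ? rinvchisq(df_e, S_e * df_e)
                       : rinvchisq(df_e + n, S_e * df_e + rss);
    }
    if (!std::isfinite(s2e) || s2e <= 0.0) stop("divergent residual variance draw");
    double dev = n * std::log(2.0 * M_PI * s2e) + rss / s2e;

    // --- store
    if (it >= burnin && ((it - burnin) % thin) == 0 && stored < nret) {
      dr_s2e[stored] = s2e;
      dr_dev[stored] = dev;
      dr_pi[stored] = piz;
      dr_mu[stored] = mu;
      for (int k = 0; k < nk; ++k) dr_s2k(stored, k) = s2k[k];
      if (per_marker_var) {
        for (int j = 0; j < p; ++j)
          dr_snpvar(stored, j) = (method == 2 && !delta[j]) ? 0.0 : s2j[j];
      } else {
        dr_snpvar(stored, 0) = s2snp;
      }
      mu_sum += mu;
      for (int j = 0; j < p; ++j) {
        m_sum[j] += m[j]; m_sumsq[j] += m[j] * m[j]; incl_sum[j] += delta[j];
      }
      for (int k = 0; k < nk; ++k)
        for (int j = 0; j < n; ++j) a_sum[k][j] += alpha[k][j];
      stored++;
    }
  }

  NumericVector m_mean(p), m_sd(p), incl(p);
  for (int j = 0; j < p; ++j) {
    m_mean[j] = m_sum[j] / stored;
    double v = m_sumsq[j] / stored - m_mean[j] * m_mean[j];
    m_sd[j] = std::sqrt(std::max(v, 0.0));
    incl[j] = incl_sum[j] / stored;
  }
  List alpha_mean(nk);
  for (int k = 0; k < nk; ++k) {
    NumericVector am(n);
    for (int j = 0; j < n; ++j) am[j] = a_sum[k][j] / stored;
    alpha_mean[k] = am;
  }

  return List::create(
    _["mu_mean"] = mu_sum / stored, _["mu_draws"] = dr_mu,
    _["m_mean"] = m_mean, _["m_sd"] = m_sd, _["inclusion"] = incl,
    _["alpha_mean"] = alpha_mean,
    _["sigma2_e"] = dr_s2e, _["sigma2_k"] = dr_s2k,
    _["snp_var"] = dr_snpvar, _["pi_zero"] = dr_pi,
    _["deviance"] = dr_dev, _["n_retained"] = stored);
}
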