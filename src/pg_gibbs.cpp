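// Polya-Gamma Gibbs sampler for survey-weighted spatial logistic regression.
//
// Model: y_i ~ Bernoulli(p_i), logit(p_i) = Z_i beta + s[k1_i] + phi[k2_i]
//        + b[d_i] + h[d_i], with the log-likelihood of record i multiplied by
//        its sampling weight w_i (pseudo-likelihood). Augmenting each record
//        with omega_i ~ PG(w_i, eta_i) makes every Gaussian block conjugate.
//
// PG(1, z) is drawn exactly with Devroye's alternating-series method; PG(b, z)
// for non-integer b (real survey weights) uses the infinite sum-of-gammas
// representation truncated at PG_TERMS terms with an analytic tail-mean
// correction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PG_T = 0.636619772367581343;      // truncation point 2/pi
static const double PISQ = 9.869604401089358619;      // pi^2
static const int PG_TERMS = 40;

// coefficient a_n(x) of the alternating-series bound for the J*(1,.) density
static double pg_coef(int n, double x) {
  double np = n + 0.5;
  if (x <= PG_T) {
    return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np * np / x);
  }
  return M_PI * np * std::exp(-np * np * PISQ * x / 2.0);
}

// inverse-Gaussian(mu, lambda = 1) via Michael-Schucany-Haas
static double rinvgauss1(double mu) {
  double v = norm_rand();
  double yv = v * v;
  double x = mu + 0.5 * mu * (mu * yv - std::sqrt(4.0 * mu * yv + mu * mu * yv * yv));
  if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
  return x;
}

// IG(1/z, 1) truncated to (0, t]
static double rtrunc_invgauss(double z, double t) {
  double mu = (z > 0) ? 1.0 / z : R_PosInf;
  if (mu > t) {
    // sample 1/X restricted to [1/t, inf) via exponential rejection, then tilt
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      double x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (std::log(unif_rand()) <= -0.5 * z * z * x) return x;
    }
  }
  for (;;) {
    double x = rinvgauss1(mu);
    if (x < t) return x;
  }
}

// standard normal CDF at x (log scale)
static double lpnorm(double x) { return R::pnorm(x, 0.0, 1.0, 1, 1); }

// exact draw from PG(1, z), Devroye / Polson-Scott-Windle
static double rpg_devroye1(double z) {
  z = std::fabs(z) * 0.5;
  double lam = PISQ / 8.0 + z * z / 2.0;     // tail exponential rate
  // probability of the exponential-tail mixture component: p / (p + q) with
  //   p = (pi / (2 lam)) exp(-lam t)
  //   q = 2 exp(-z) * P(IG(1/z, 1) <= t)   (IG CDF written out, log scale)
  double rt = std::sqrt(PG_T);
  double lq1 = -z + lpnorm((PG_T * z - 1.0) / rt);
  double lq2 = z + lpnorm(-(PG_T * z + 1.0) / rt);
  double m = std::max(lq1, lq2);
  double log_q_over_p = std::log(4.0 / M_PI) + std::log(lam) + lam * PG_T +
                        m + std::log(std::exp(lq1 - m) + std::exp(lq2 - m));
  double ratio = 1.0 / (1.0 + std::exp(log_q_over_p));

  for (;;) {
    double x;
    if (unif_rand() < ratio) {
      x = PG_T + exp_rand() / lam;           // truncated exponential tail
    } else {
      x = rtrunc_invgauss(z, PG_T);          // truncated inverse-Gaussian head
    }
    // alternating-series accept/reject
    double s = pg_coef(0, x);
    double yu = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_coef(n, x);
        if (yu <= s) return 0.25 * x;
      } else {
        s += pg_coef(n, x);
        if (yu > s) break;                   // reject; redraw proposal
      }
    }
  }
}

// PG(b, z) for real b > 0: truncated sum-of-gammas with tail-mean correction
static double rpg_series(double b, double z) {
  double c = z * z / 2.0;
  double out = 0.0;
  for (int k = 1; k <= PG_TERMS; ++k) {
    double denom = 2.0 * PISQ * (k - 0.5) * (k - 0.5) + c;
    out += R::rgamma(b, 1.0) / denom;
  }
  // E of the dropped tail: b * int_T^inf du / (2 pi^2 u^2 + c)
  double tail;
  if (c < 1e-12) {
    tail = b / (2.0 * PISQ * PG_TERMS);
  } else {
    double a = std::sqrt(2.0 * PISQ / c);
    tail = b / std::sqrt(2.0 * PISQ * c) * (M_PI_2 - std::atan(PG_TERMS * a));
  }
  return out + tail;
}

static double rpg(double b, double z) {
  if (std::fabs(b - 1.0) < 1e-12) return rpg_devroye1(z);
  double ib = std::nearbyint(b);
  if (std::fabs(b - ib) < 1e-12 && ib >= 1.0 && ib <= 4.0) {
    double s = 0.0;
    for (int k = 0; k < (int)ib; ++k) s += rpg_devroye1(z);
    return s;
  }
  return rpg_series(b, z);
}

//' @title Polya-Gamma random draws (internal)
//' @description Draws from PG(b, z); exact for b = 1 (Devroye sampler),
//'   truncated-series with tail correction otherwise. Exposed for testing.
//' @param n number of draws
//' @param b shape (tilting) parameter, positive real
//' @param z tilting parameter
//' @keywords internal
// [[Rcpp::export]]
NumericVector rpg_cpp(int n, double b, double z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg(b, z);
  return out;
}

// sample from N(P^{-1} r, P^{-1}) given canonical parameters
static arma::vec rmvn_canonical(const arma::mat& P, const arma::vec& r) {
  arma::mat U = arma::chol(P);                       // P = U' U
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), r));
  arma::vec zdraw(r.n_elem);
  for (arma::uword i = 0; i < zdraw.n_elem; ++i) zdraw[i] = norm_rand();
  return mu + arma::solve(arma::trimatu(U), zdraw);
}

// log prior density (up to constants) of a variance-component prior placed on
// the sd sigma. family: 1 half-normal(scale), 2 half-Cauchy(scale),
// 3 half-t(df, scale), 4 uniform(0, upper), 5 PC/exponential(rate from u, alpha)
static double log_sd_prior(int family, double p1, double p2, double sigma) {
  switch (family) {
  case 1: return -sigma * sigma / (2.0 * p1 * p1);
  case 2: return -std::log1p(sigma * sigma / (p1 * p1));
  case 3: return -0.5 * (p1 + 1.0) * std::log1p(sigma * sigma / (p1 * p2 * p2));
  case 4: return (sigma < p1) ? 0.0 : R_NegInf;
  case 5: { double lam = -std::log(p2) / p1; return -lam * sigma; }
  default: stop("unknown sd-prior family");
  }
  return R_NegInf;
}

// update one precision parameter tau given quadratic form q = x' Q x and
// GMRF rank rnk. Gamma family (0) is conjugate; sd-scale families use a
// random-walk Metropolis step on log sigma.
static double update_tau(double tau, int family, double p1, double p2,
                         double q, double rnk) {
  if (family == 0) {
    // prior Gamma(a1 = p1, rate a2 = p2) on tau
    return R::rgamma(p1 + rnk / 2.0, 1.0 / (p2 + q / 2.0));
  }
  double lsig = -0.5 * std::log(tau);
  auto logpost = [&](double ls) {
    double sig = std::exp(ls);
    double tt = std::exp(-2.0 * ls);
    // GMRF kernel + prior on sigma + Jacobian d sigma / d log sigma
    return -rnk * ls - tt * q / 2.0 + log_sd_prior(family, p1, p2, sig) + ls;
  };
  double lp0 = logpost(lsig);
  for (int rep = 0; rep < 2; ++rep) {
    double prop = lsig + 0.35 * norm_rand();
    double lp1 = logpost(prop);
    if (std::log(unif_rand()) < lp1 - lp0) { lsig = prop; lp0 = lp1; }
  }
  return std::exp(-2.0 * lsig);
}

// [[Rcpp::export]]
List pg_gibbs_cpp(const arma::vec& y, const arma::vec& w, const arma::mat& Z,
                  const arma::ivec& k1, const arma::mat& Q1, double rnk1,
                  const arma::ivec& k2, const arma::mat& Q2, double rnk2,
                  const arma::ivec& dist, const arma::mat& Qb,
                  bool use_car, bool use_iid,
                  double beta_var,
                  const IntegerVector& tau_family,
                  const NumericVector& tau_p1, const NumericVector& tau_p2,
                  int n_iter, int n_burn) {
  const int n = y.n_elem;
  const int p = Z.n_cols;
  const int K1 = Q1.n_rows, K2 = Q2.n_rows;
  const int J = Qb.n_rows;
  const bool has_s1 = K1 > 0, has_s2 = K2 > 0;
  // rnk1/rnk2: rank of the RW penalty (K - 1 for RW1, K - 2 for RW2);
  // the ICAR penalty on a connected graph has rank J - 1, the IID part is full.
  const double rnkb = use_car ? (double)(J - 1) : 0.0;

  arma::vec beta(p, arma::fill::zeros);
  arma::vec s1(std::max(K1, 1), arma::fill::zeros);
  arma::vec s2(std::max(K2, 1), arma::fill::zeros);
  arma::vec b(std::max(J, 1), arma::fill::zeros);
  arma::vec h(std::max(J, 1), arma::fill::zeros);
  double tau_s1 = 1.0, tau_s2 = 1.0, tau_b = 1.0, tau_h = 1.0;

  arma::vec eta = Z * beta;
  arma::vec omega(n), kappa(n);
  for (int i = 0; i < n; ++i) kappa[i] = w[i] * (y[i] - 0.5);

  // Joint scale move on one GMRF block: propose (x, tau) -> (c x, tau / c^2),
  // which leaves the Gaussian kernel's quadratic form invariant and lets the
  // chain cross between small-sigma and large-sigma regimes that the
  // conditional tau | x update alone traverses very slowly (the field and its
  // scale are rescaled together, in the spirit of ancillarity-sufficiency
  // interweaving). The weighted Bernoulli log-likelihood difference is exact.
  auto scale_move = [&](arma::vec& x, double& tau, const arma::ivec& idx,
                        double rnk, int fam, double p1, double p2) {
    double lc = 0.4 * norm_rand();
    double c = std::exp(lc);
    double dll = 0.0;
    for (int i = 0; i < n; ++i) {
      double e0 = eta[i];
      double e1 = e0 + (c - 1.0) * x[idx[i]];
      double lse0 = (e0 > 0) ? e0 + std::log1p(std::exp(-e0)) : std::log1p(std::exp(e0));
      double lse1 = (e1 > 0) ? e1 + std::log1p(std::exp(-e1)) : std::log1p(std::exp(e1));
      dll += w[i] * (y[i] * (e1 - e0) - (lse1 - lse0));
    }
    double dim = (double)x.n_elem;
    double dlp;
    if (fam == 0) {
      // (x, tau) parameterization with a Gamma(p1, rate p2) prior on tau
      double tau_new = tau / (c * c);
      dlp = -rnk * lc + (p1 - 1.0) * std::log(tau_new / tau) -
            p2 * (tau_new - tau) + (dim - 2.0) * lc;
    } else {
      // (x, log sigma) parameterization with an sd-scale prior
      double sig = 1.0 / std::sqrt(tau);
      dlp = -rnk * lc + log_sd_prior(fam, p1, p2, c * sig) -
            log_sd_prior(fam, p1, p2, sig) + (dim + 1.0) * lc;
    }
    if (std::log(unif_rand()) < dll + dlp) {
      for (int i = 0; i < n; ++i) eta[i] += (c - 1.0) * x[idx[i]];
      x *= c;
      tau /= c * c;
    }
  };

  const int S = n_iter - n_burn;
  arma::mat beta_st(S, p), s1_st(S, std::max(K1, 0)), s2_st(S, std::max(K2, 0));
  arma::mat b_st(S, use_car ? J : 0), h_st(S, use_iid ? J : 0);
  arma::mat sig_st(S, 4);

  arma::mat Ip = arma::eye(p, p) / beta_var;

  for (int it = 0; it < n_iter; ++it) {
    // --- Polya-Gamma latents
    for (int i = 0; i < n; ++i) omega[i] = rpg(w[i], eta[i]);

    // --- fixed effects block
    {
      arma::vec o = eta - Z * beta;
      arma::mat P = Z.t() * (Z.each_col() % omega) + Ip;
      arma::vec r = Z.t() * (kappa - omega % o);
      arma::vec bn = rmvn_canonical(P, r);
      eta += Z * (bn - beta);
      beta = bn;
    }

    // --- smooth blocks (centered; level transferred to intercept)
    if (has_s1) {
      arma::vec a(K1, arma::fill::zeros), r(K1, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        int k = k1[i];
        a[k] += omega[i];
        r[k] += kappa[i] - omega[i] * (eta[i] - s1[k]);
      }
      arma::mat P = tau_s1 * Q1; P.diag() += a;
      arma::vec sn = rmvn_canonical(P, r);
      for (int i = 0; i < n; ++i) eta[i] += sn[k1[i]] - s1[k1[i]];
      double m = arma::mean(sn);
      s1 = sn - m; beta[0] += m;
      tau_s1 = update_tau(tau_s1, tau_family[0], tau_p1[0], tau_p2[0],
                          arma::as_scalar(s1.t() * Q1 * s1), rnk1);
      scale_move(s1, tau_s1, k1, rnk1, tau_family[0], tau_p1[0], tau_p2[0]);
    }
    if (has_s2) {
      arma::vec a(K2, arma::fill::zeros), r(K2, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        int k = k2[i];
        a[k] += omega[i];
        r[k] += kappa[i] - omega[i] * (eta[i] - s2[k]);
      }
      arma::mat P = tau_s2 * Q2; P.diag() += a;
      arma::vec sn = rmvn_canonical(P, r);
      for (int i = 0; i < n; ++i) eta[i] += sn[k2[i]] - s2[k2[i]];
      double m = arma::mean(sn);
      s2 = sn - m; beta[0] += m;
      tau_s2 = update_tau(tau_s2, tau_family[1], tau_p1[1], tau_p2[1],
                          arma::as_scalar(s2.t() * Q2 * s2), rnk2);
      scale_move(s2, tau_s2, k2, rnk2, tau_family[1], tau_p1[1], tau_p2[1]);
    }

    // --- structured spatial block (ICAR), hard sum-to-zero via transfer
    if (use_car) {
      arma::vec a(J, arma::fill::zeros), r(J, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        int j = dist[i];
        a[j] += omega[i];
        r[j] += kappa[i] - omega[i] * (eta[i] - b[j]);
      }
      arma::mat P = tau_b * Qb; P.diag() += a;
      arma::vec bn = rmvn_canonical(P, r);
      for (int i = 0; i < n; ++i) eta[i] += bn[dist[i]] - b[dist[i]];
      double m = arma::mean(bn);
      b = bn - m; beta[0] += m;
      tau_b = update_tau(tau_b, tau_family[2], tau_p1[2], tau_p2[2],
                         arma::as_scalar(b.t() * Qb * b), rnkb);
      scale_move(b, tau_b, dist, rnkb, tau_family[2], tau_p1[2], tau_p2[2]);
    }

    // --- unstructured district block (IID), unconstrained
    if (use_iid) {
      arma::vec a(J, arma::fill::zeros), r(J, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        int j = dist[i];
        a[j] += omega[i];
        r[j] += kappa[i] - omega[i] * (eta[i] - h[j]);
      }
      arma::vec hn(J);
      for (int j = 0; j < J; ++j) {
        double prec = tau_h + a[j];
        hn[j] = r[j] / prec + norm_rand() / std::sqrt(prec);
      }
      for (int i = 0; i < n; ++i) eta[i] += hn[dist[i]] - h[dist[i]];
      h = hn;
      tau_h = update_tau(tau_h, tau_family[3], tau_p1[3], tau_p2[3],
                         arma::dot(h, h), (double)J);
      scale_move(h, tau_h, dist, (double)J, tau_family[3], tau_p1[3], tau_p2[3]);
    }

    if (it >= n_burn) {
      int s = it - n_burn;
      beta_st.row(s) = beta.t();
      if (has_s1) s1_st.row(s) = s1.t();
      if (has_s2) s2_st.row(s) = s2.t();
      if (use_car) b_st.row(s) = b.t();
      if (use_iid) h_st.row(s) = h.t();
      sig_st(s, 0) = has_s1 ? 1.0 / std::sqrt(tau_s1) : NA_REAL;
      sig_st(s, 1) = has_s2 ? 1.0 / std::sqrt(tau_s2) : NA_REAL;
      sig_st(s, 2) = use_car ? 1.0 / std::sqrt(tau_b) : NA_REAL;
      sig_st(s, 3) = use_iid ? 1.0 / std::sqrt(tau_h) : NA_REAL;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["beta"] = beta_st, _["s1"] = s1_st, _["s2"] = s2_st,
    _["b"] = b_st, _["h"] = h_st, _["sigma"] = sig_st);
}
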