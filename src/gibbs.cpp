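// Gibbs sampler for the latent-truth probit model with two error-prone
// reporting sources.
//
// Model: D_i ~ Bernoulli(Phi(x_i' alpha));  y_ji | D_i ~ Bernoulli with
// P(y=1|D=1) = Sn_j and P(y=1|D=0) = 1 - Sp_j, sources conditionally
// independent given D.  Probit coefficients are updated by Albert-Chib
// truncated-normal data augmentation; Sn/Sp have conjugate Beta full
// conditionals truncated to Sn + Sp > 1 (label-switching guard).
//
// Uses R's RNG throughout so chains are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clamp01(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}

// N(m, 1) truncated to (0, Inf) via inverse CDF
static inline double rtnorm_pos(double m) {
  double p0 = R::pnorm(0.0, m, 1.0, 1, 0);
  double p = clamp01(p0 + R::unif_rand() * (1.0 - p0));
  return R::qnorm(p, m, 1.0, 1, 0);
}

// N(m, 1) truncated to (-Inf, 0]
static inline double rtnorm_neg(double m) {
  double p0 = R::pnorm(0.0, m, 1.0, 1, 0);
  double p = clamp01(R::unif_rand() * p0);
  return R::qnorm(p, m, 1.0, 1, 0);
}

// [[Rcpp::export]]
List gibbs_chain(const arma::mat& X, const arma::ivec& y1, const arma::ivec& y2,
                 const int n_iter, const double coef_sd,
                 const double sn_a, const double sn_b,
                 const double sp_a, const double sp_b,
                 const arma::vec& alpha_init, const arma::vec& acc_init) {
  const int n = X.n_rows;
  const int p = X.n_cols;

  arma::mat prec = X.t() * X;
  prec.diag() += 1.0 / (coef_sd * coef_sd);
  const arma::mat Ru = arma::chol(prec);  // prec = Ru' Ru

  arma::vec alpha = alpha_init;
  double sn1 = acc_init(0), sp1 = acc_init(1);
  double sn2 = acc_init(2), sp2 = acc_init(3);

  arma::vec eta = X * alpha;
  arma::vec z(n);
  arma::ivec D(n);

  NumericVector prev(n_iter), dev(n_iter);
  NumericMatrix coefs(n_iter, p), acc(n_iter, 4);

  for (int it = 0; it < n_iter; ++it) {
    // --- sample latent D and record the deviance of the *previous* draw
    // (alpha, Sn, Sp currently in scope are the values stored at it-1)
    double sumD = 0.0, loglik = 0.0;
    int n11_1 = 0, n10_1 = 0, n01_1 = 0, n00_1 = 0;
    int n11_2 = 0, n10_2 = 0, n01_2 = 0, n00_2 = 0;
    for (int i = 0; i < n; ++i) {
      double pi = R::pnorm(eta(i), 0.0, 1.0, 1, 0);
      double l1 = (y1(i) ? sn1 : 1.0 - sn1) * (y2(i) ? sn2 : 1.0 - sn2);
      double l0 = (y1(i) ? 1.0 - sp1 : sp1) * (y2(i) ? 1.0 - sp2 : sp2);
      double a = pi * l1, b = (1.0 - pi) * l0;
      double tot = a + b;
      loglik += std::log(tot > 1e-300 ? tot : 1e-300);
      double pr = tot > 0 ? a / tot : pi;
      int d = (R::unif_rand() < pr) ? 1 : 0;
      D(i) = d;
      sumD += d;
      z(i) = d ? rtnorm_pos(eta(i)) : rtnorm_neg(eta(i));
      if (d) {
        if (y1(i)) ++n11_1; else ++n10_1;
        if (y2(i)) ++n11_2; else ++n10_2;
      } else {
        if (y1(i)) ++n01_1; else ++n00_1;
        if (y2(i)) ++n01_2; else ++n00_2;
      }
    }
    if (it > 0) dev(it - 1) = -2.0 * loglik;

    // --- probit coefficients by data augmentation
    arma::vec bvec = X.t() * z;
    arma::vec mu = arma::solve(arma::trimatu(Ru),
                               arma::solve(arma::trimatl(Ru.t()), bvec));
    arma::vec epsv(p);
    for (int j = 0; j < p; ++j) epsv(j) = R::norm_rand();
    alpha = mu + arma::solve(arma::trimatu(Ru), epsv);
    eta = X * alpha;

    // --- reporting parameters: Beta full conditionals with Sn+Sp>1 guard
    double s1 = sn1, t1 = sp1;
    for (int t = 0; t < 100; ++t) {
      s1 = R::rbeta(sn_a + n11_1, sn_b + n10_1);
      t1 = R::rbeta(sp_a + n00_1, sp_b + n01_1);
      if (s1 + t1 > 1.0) break;
      if (t == 99) { s1 = sn1; t1 = sp1; }
    }
    sn1 = clamp01(s1); sp1 = clamp01(t1);
    double s2 = sn2, t2 = sp2;
    for (int t = 0; t < 100; ++t) {
      s2 = R::rbeta(sn_a + n11_2, sn_b + n10_2);
      t2 = R::rbeta(sp_a + n00_2, sp_b + n01_2);
      if (s2 + t2 > 1.0) break;
      if (t == 99) { s2 = sn2; t2 = sp2; }
    }
    sn2 = clamp01(s2); sp2 = clamp01(t2);

    prev(it) = sumD / n;
    for (int j = 0; j < p; ++j) coefs(it, j) = alpha(j);
    acc(it, 0) = sn1; acc(it, 1) = sp1; acc(it, 2) = sn2; acc(it, 3) = sp2;
  }

  // deviance of the final draw needs one extra likelihood pass
  double loglik = 0.0;
  for (int i = 0; i < n; ++i) {
    double pi = R::pnorm(eta(i), 0.0, 1.0, 1, 0);
    double l1 = (y1(i) ? sn1 : 1.0 - sn1) * (y2(i) ? sn2 : 1.0 - sn2);
    double l0 = (y1(i) ? 1.0 - sp1 : sp1) * (y2(i) ? 1.0 - sp2 : sp2);
    double tot = pi * l1 + (1.0 - pi) * l0;
    loglik += std::log(tot > 1e-300 ? tot : 1e-300);
  }
  dev(n_iter - 1) = -2.0 * loglik;

  return List::create(_["prevalence"] = prev, _["coefficients"] = coefs,
                      _["accuracy"] = acc, _["deviance"] = dev);
}
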