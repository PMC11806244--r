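// Gibbs sampler for the Bayesian instrumental-variable estimator.
//
// Model (two active arms, all-or-nothing compliance):
//   stage 1:  C0_i ~ N(x_i' th0, s0^2),  C1_i ~ N(x_i' th1, s1^2)
//   stage 2:  Y_i  ~ N(aY + bC0 * (x_i' th0) + bC1 * (x_i' th1)
//                        [+ bX * X_i], sY^2)
// with a normal prior on bC0 (the effect of standard treatment vs. none)
// and diffuse priors elsewhere.  Stage 1 is modularized: (th, s^2) are
// sampled from their own conjugate posterior, without outcome feedback, and
// plugged into the stage-2 conditional updates.  The stage-1 designs x_i
// take finitely many values (the (Z, X) cells), so every full conditional
// depends on the data only through per-cell counts and sums; each update is
// O(#cells).
//
// Inverse-gamma(ig_a, ig_b) priors on the three error variances keep the
// posterior proper.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec draw_mvn_precision(const arma::mat& A, const arma::vec& b) {
  // N(A^{-1} b, A^{-1}) via upper Cholesky of the precision matrix
  arma::mat R = arma::chol(A);          // A = R' R
  arma::vec mu = arma::solve(A, b);
  arma::vec z(mu.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

static double draw_inv_gamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".gibbs_iv_bayes")]]
List gibbs_iv_bayes(const arma::mat& Xc,     // ncell x p1 stage-1 design
                    const arma::vec& xcov,   // ncell, observed covariate X
                    const arma::vec& nc,     // ncell, cell counts
                    const arma::vec& SY,     // ncell, sum of Y
                    const arma::vec& SYY,    // ncell, sum of Y^2
                    const arma::vec& SC0,    // ncell, sum of C0 (= sum C0^2)
                    const arma::vec& SC1,    // ncell, sum of C1
                    bool include_x,          // X in stage 2?
                    double prior_mean, double prior_sd,
                    int n_chains, int n_iter, int n_warmup,
                    int variant,             // 0 plugin, 1 cut, 2 joint
                    const arma::vec& th0_fix, const arma::vec& th1_fix,
                    double s0_fix, double s1_fix,
                    double ig_a, double ig_b) {
  const int ncell = Xc.n_rows, p1 = Xc.n_cols;
  const int p2 = include_x ? 4 : 3;
  const double n = arma::accu(nc);
  const double prior_prec = 1.0 / (prior_sd * prior_sd);

  // stage-1 cross-products shared by every update
  arma::mat M(p1, p1, arma::fill::zeros);
  arma::vec t0(p1, arma::fill::zeros), t1(p1, arma::fill::zeros);
  for (int c = 0; c < ncell; ++c) {
    arma::vec x = Xc.row(c).t();
    M += nc(c) * (x * x.t());
    t0 += x * SC0(c);
    t1 += x * SC1(c);
  }
  // OLS starting values for the stage-1 coefficients
  arma::vec th0_ols = arma::solve(M, t0), th1_ols = arma::solve(M, t1);

  const int keep = n_iter - n_warmup;
  arma::mat beta_out(keep * n_chains, p2);
  arma::vec sY_out(keep * n_chains);
  IntegerVector chain_out(keep * n_chains);

  RNGScope scope;
  double ybar = arma::accu(SY) / n;
  double yvar = arma::accu(SYY) / n - ybar * ybar;
  if (yvar < 1e-8) yvar = 1e-8;

  const bool plugin = variant == 0;
  int row = 0;
  for (int ch = 0; ch < n_chains; ++ch) {
    arma::vec th0 = plugin ? th0_fix : th0_ols;
    arma::vec th1 = plugin ? th1_fix : th1_ols;
    double s0 = plugin ? s0_fix * s0_fix : 0.05;
    double s1 = plugin ? s1_fix * s1_fix : 0.05;
    double sY = yvar;
    // overdispersed starting values for the structural coefficients
    arma::vec beta(p2, arma::fill::zeros);
    beta(0) = ybar + 0.5 * R::norm_rand();
    beta(1) = prior_mean + prior_sd * R::norm_rand();
    beta(2) = prior_mean + prior_sd * R::norm_rand();

    for (int it = 0; it < n_iter; ++it) {
      // predicted compliances per cell under current stage-1 draws
      arma::vec c0hat = Xc * th0, c1hat = Xc * th1;

      if (variant == 1) {
        // stage-1 coefficients from their own (modularized) posterior:
        // th | s^2 ~ N(OLS, s^2 M^{-1}); no outcome feedback, so stage-1
        // uncertainty propagates into the contrast without the stage-2
        // likelihood re-estimating the compliance model
        th0 = draw_mvn_precision(M / s0, t0 / s0);
        th1 = draw_mvn_precision(M / s1, t1 / s1);
        c0hat = Xc * th0;
        c1hat = Xc * th1;
      } else if (variant == 2) {
        // fully joint: the outcome likelihood also informs the stage-1
        // coefficients (Y depends on x' th through bC0, bC1)
        double bC0 = beta(1), bC1 = beta(2);
        arma::mat A = (1.0 / s0 + bC0 * bC0 / sY) * M;
        arma::vec b = t0 / s0;
        for (int c = 0; c < ncell; ++c) {
          double mu_rest = beta(0) + bC1 * c1hat(c) +
            (include_x ? beta(3) * xcov(c) : 0.0);
          b += (bC0 / sY) * Xc.row(c).t() * (SY(c) - nc(c) * mu_rest);
        }
        th0 = draw_mvn_precision(A, b);
        c0hat = Xc * th0;
        arma::mat A1 = (1.0 / s1 + bC1 * bC1 / sY) * M;
        arma::vec b1 = t1 / s1;
        for (int c = 0; c < ncell; ++c) {
          double mu_rest = beta(0) + bC0 * c0hat(c) +
            (include_x ? beta(3) * xcov(c) : 0.0);
          b1 += (bC1 / sY) * Xc.row(c).t() * (SY(c) - nc(c) * mu_rest);
        }
        th1 = draw_mvn_precision(A1, b1);
        c1hat = Xc * th1;
      }

      // beta | rest : normal linear model with prior on bC0
      arma::mat WtW(p2, p2, arma::fill::zeros);
      arma::vec Wty(p2, arma::fill::zeros);
      for (int c = 0; c < ncell; ++c) {
        arma::vec w(p2);
        w(0) = 1.0; w(1) = c0hat(c); w(2) = c1hat(c);
        if (include_x) w(3) = xcov(c);
        WtW += nc(c) * (w * w.t());
        Wty += w * SY(c);
      }
      arma::mat A2 = WtW / sY;
      A2(1, 1) += prior_prec;
      arma::vec b2 = Wty / sY;
      b2(1) += prior_mean * prior_prec;
      beta = draw_mvn_precision(A2, b2);

      if (!plugin) {
        // residual variances of the stage-1 models (C0, C1 binary)
        double ssr0 = 0.0, ssr1 = 0.0;
        for (int c = 0; c < ncell; ++c) {
          ssr0 += SC0(c) * (1.0 - 2.0 * c0hat(c)) + nc(c) * c0hat(c) * c0hat(c);
          ssr1 += SC1(c) * (1.0 - 2.0 * c1hat(c)) + nc(c) * c1hat(c) * c1hat(c);
        }
        s0 = draw_inv_gamma(ig_a + n / 2.0, ig_b + std::max(ssr0, 0.0) / 2.0);
        s1 = draw_inv_gamma(ig_a + n / 2.0, ig_b + std::max(ssr1, 0.0) / 2.0);
      }

      double ssrY = 0.0;
      for (int c = 0; c < ncell; ++c) {
        double mu = beta(0) + beta(1) * c0hat(c) + beta(2) * c1hat(c) +
          (include_x ? beta(3) * xcov(c) : 0.0);
        ssrY += SYY(c) - 2.0 * mu * SY(c) + nc(c) * mu * mu;
      }
      sY = draw_inv_gamma(ig_a + n / 2.0, ig_b + std::max(ssrY, 0.0) / 2.0);

      if (it >= n_warmup) {
        beta_out.row(row) = beta.t();
        sY_out(row) = sY;
        chain_out[row] = ch + 1;
        ++row;
      }
    }
  }

  return List::create(_["beta"] = beta_out, _["sigmaY2"] = sY_out,
                      _["chain"] = chain_out);
}
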