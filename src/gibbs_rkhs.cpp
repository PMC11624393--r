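// Gibbs sampler for the reliability-weighted kernel regression
//   y = X b + g + e,  g = U z with K = U diag(d) U',  z_j ~ N(0, d_j sg2),
//   e_i ~ N(0, se2 / w_i)  (w_i = record reliability)
// Single-site updates of the spectral coordinates z with an incrementally
// maintained training residual; b drawn jointly from its multivariate-normal
// full conditional (flat prior); variance components from scaled-inverse-
// chi-square full conditionals. Uses R's RNG so set.seed() governs the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_rkhs_cpp(const arma::mat& Ut,   // n_train x m eigenvectors (train rows)
                    const arma::mat& Ua,   // n_all x m eigenvectors (all rows)
                    const arma::vec& d,    // m retained eigenvalues
                    const arma::mat& Xt,   // n_train x q fixed-effect design
                    const arma::vec& yt,   // n_train phenotypes
                    const arma::vec& wt,   // n_train reliabilities
                    int n_iter, int burn_in, int thin,
                    double df_g, double df_e,
                    double scale_g, double scale_e,
                    double init_sg2, double init_se2,
                    bool fix_sg2, bool fix_se2,
                    bool store_g) {
  const int nt = Ut.n_rows, m = Ut.n_cols, q = Xt.n_cols,
            na = Ua.n_rows;
  RNGScope scope;

  arma::mat WU = Ut.each_col() % wt;            // n_train x m
  arma::vec cj = arma::sum(Ut % WU, 0).t();     // sum_i w_i U_ij^2
  arma::mat XtWX = Xt.t() * (Xt.each_col() % wt);
  arma::mat Cx = arma::chol(XtWX);              // upper: Cx'Cx = X'WX

  double sg2 = init_sg2, se2 = init_se2;
  arma::vec b(q, arma::fill::zeros), z(m, arma::fill::zeros);
  arma::vec e = yt;                              // residual y - Xb - Ut z

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat B(n_keep, q), G;
  arma::vec SG2(n_keep), SE2(n_keep);
  arma::vec g_sum(na, arma::fill::zeros), g_ss(na, arma::fill::zeros);
  if (store_g) G.set_size(n_keep, na);

  const bool zero_genetic = fix_sg2 && sg2 <= 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects: b | rest ~ N((X'WX)^{-1} X'W r, se2 (X'WX)^{-1})
    arma::vec r_full = e + Xt * b;               // y - U z
    arma::vec mu = arma::solve(XtWX, Xt.t() * (wt % r_full),
                               arma::solve_opts::likely_sympd);
    arma::vec eps(q);
    for (int k = 0; k < q; ++k) eps(k) = R::norm_rand();
    b = mu + std::sqrt(se2) * arma::solve(arma::trimatu(Cx), eps);
    e = r_full - Xt * b;

    // --- spectral coordinates z_j, single site
    if (!zero_genetic) {
      for (int j = 0; j < m; ++j) {
        double zo = z(j);
        double rhs = arma::dot(WU.col(j), e) + cj(j) * zo;
        double prec = cj(j) / se2 + 1.0 / (d(j) * sg2);
        double mean = (rhs / se2) / prec;
        double zn = mean + R::norm_rand() / std::sqrt(prec);
        z(j) = zn;
        e -= Ut.col(j) * (zn - zo);
      }
    }

    // --- variance components, scaled-inverse-chi-square full conditionals
    if (!fix_sg2) {
      double ssq = arma::dot(z % z, 1.0 / d);
      sg2 = (ssq + df_g * scale_g) / R::rchisq(m + df_g);
    }
    if (!fix_se2) {
      double sse = arma::dot(wt, e % e);
      se2 = (sse + df_e * scale_e) / R::rchisq(nt + df_e);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      arma::vec g = Ua * z;
      B.row(kept) = b.t();
      SG2(kept) = sg2;
      SE2(kept) = se2;
      g_sum += g;
      g_ss += g % g;
      if (store_g) G.row(kept) = g.t();
      ++kept;
    }
  }

  arma::vec g_mean = g_sum / kept;
  arma::vec g_var = g_ss / kept - g_mean % g_mean;
  g_var.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::vec g_sd = arma::sqrt(g_var * ((double)kept / std::max(kept - 1, 1)));

  List out = List::create(
    _["b_draws"] = B, _["sigma_g2_draws"] = SG2, _["sigma_e2_draws"] = SE2,
    _["g_mean"] = g_mean, _["g_sd"] = g_sd, _["n_kept"] = kept);
  if (store_g) out["g_draws"] = G;
  return out;
}
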