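// VMD ADMM iteration on the positive half-spectrum.
// Mirrors the formulation in R/vmd.R: Wiener-filtered mode updates with
// denominator 1 + 2*alpha*(w - w_k)^2, spectral-centroid carrier updates,
// optional Lagrange multiplier, convergence on summed relative mode change.
// Real and imaginary parts are carried separately: the mode filter is real,
// so complex division/abs never has to be invoked.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".vmd_iterate")]]
Rcpp::List vmd_iterate(const arma::cx_vec& f_hat_plus, const arma::vec& fp,
                       arma::vec omega, double alpha, double tau, double tol,
                       int max_iter) {
  const uword np = fp.n_elem;
  const uword K = omega.n_elem;
  const vec fr = real(f_hat_plus);
  const vec fi = imag(f_hat_plus);
  mat ur(np, K, fill::zeros), ui(np, K, fill::zeros);
  mat pr(np, K, fill::zeros), pi(np, K, fill::zeros);
  vec lr(np, fill::zeros), li(np, fill::zeros);
  vec sum_r(np), sum_i(np), inv(np), pw(np);
  bool converged = false;
  int it = 0;
  double last_change = 0.0;
  while (it < max_iter) {
    ++it;
    pr = ur; pi = ui;
    sum_r = sum(ur, 1);
    sum_i = sum(ui, 1);
    for (uword k = 0; k < K; ++k) {
      sum_r -= ur.col(k);
      sum_i -= ui.col(k);
      inv = 1.0 / (1.0 + 2.0 * alpha * square(fp - omega(k)));
      ur.col(k) = (fr - sum_r + lr / 2.0) % inv;
      ui.col(k) = (fi - sum_i + li / 2.0) % inv;
      pw = square(ur.col(k)) + square(ui.col(k));
      const double s = accu(pw);
      if (s > datum::eps) omega(k) = dot(fp, pw) / s;
      sum_r += ur.col(k);
      sum_i += ui.col(k);
    }
    if (tau != 0.0) {
      lr += tau * (fr - sum(ur, 1));
      li += tau * (fi - sum(ui, 1));
    }
    const double dnum = accu(square(ur - pr)) + accu(square(ui - pi));
    const double dden = accu(square(pr)) + accu(square(pi));
    if (dden > 0.0) {
      last_change = dnum / dden;
      if (last_change < tol) { converged = true; break; }
    }
  }
  cx_mat u(ur, ui);
  return Rcpp::List::create(Rcpp::Named("u_hat") = u,
                            Rcpp::Named("omega") = omega,
                            Rcpp::Named("n_iter") = it,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("last_change") = last_change);
}
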