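// Penalized IRLS for a Poisson log-link mixed model with up to two crossed
// random intercepts (size class, prey item), plus the Laplace marginal
// log-likelihood at the joint (beta, u) mode. The outer search over the
// variance components stays in R; this routine is the per-evaluation inner
// loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Joint penalized Poisson log-likelihood:
//   Q(theta) = sum(y * eta - exp(eta) - lgamma(y + 1)) - 0.5 * theta' P theta
// with P zero on fixed effects and 1/sigma^2 on each random block.
static double objective(const arma::vec& y, const arma::vec& eta,
                        const arma::vec& theta, const arma::vec& pen) {
  double ll = arma::accu(y % eta - arma::exp(eta));
  double penalty = 0.5 * arma::accu(pen % arma::square(theta));
  return ll - penalty;
}

// [[Rcpp::export]]
List cpp_pirls(const arma::mat& X, const arma::vec& y, const arma::vec& offset,
               const arma::ivec& class_idx, const arma::ivec& item_idx,
               const double sigma_class, const double sigma_item,
               const arma::vec& start, const double tol, const int maxit,
               const bool want_hessian) {
  const arma::uword n = y.n_elem;
  const arma::uword p = X.n_cols;
  const bool has_class = class_idx.n_elem == n && sigma_class > 0.0;
  const bool has_item = item_idx.n_elem == n && sigma_item > 0.0;
  const arma::uword qc = has_class ? (arma::uword)class_idx.max() : 0;
  const arma::uword qi = has_item ? (arma::uword)item_idx.max() : 0;
  const arma::uword m = p + qc + qi;

  // dense design [X | Z_class | Z_item]
  arma::mat M(n, m, arma::fill::zeros);
  M.cols(0, p - 1) = X;
  if (has_class)
    for (arma::uword r = 0; r < n; ++r)
      M(r, p + class_idx(r) - 1) = 1.0;
  if (has_item)
    for (arma::uword r = 0; r < n; ++r)
      M(r, p + qc + item_idx(r) - 1) = 1.0;

  arma::vec pen(m, arma::fill::zeros);
  if (has_class)
    pen.subvec(p, p + qc - 1).fill(1.0 / (sigma_class * sigma_class));
  if (has_item)
    pen.subvec(p + qc, m - 1).fill(1.0 / (sigma_item * sigma_item));

  arma::vec theta = start.n_elem == m ? start
                                      : arma::vec(m, arma::fill::zeros);
  arma::vec eta = M * theta + offset;
  double q_old = objective(y, eta, theta, pen);
  bool converged = false, diverged = false;
  int iter = 0;

  for (iter = 1; iter <= maxit; ++iter) {
    arma::vec mu = arma::exp(eta);
    arma::vec grad = M.t() * (y - mu) - pen % theta;
    arma::mat H = M.t() * (M.each_col() % mu);
    H.diag() += pen;
    arma::vec step;
    if (!arma::solve(step, H, grad, arma::solve_opts::likely_sympd)) {
      diverged = true;
      break;
    }
    // step halving keeps the penalized objective non-decreasing
    double q_new = -arma::datum::inf;
    arma::vec theta_new;
    double fac = 1.0;
    for (int h = 0; h < 30; ++h) {
      theta_new = theta + fac * step;
      arma::vec eta_new = M * theta_new + offset;
      if (eta_new.max() > 300.0) { fac *= 0.5; continue; }
      q_new = objective(y, eta_new, theta_new, pen);
      if (std::isfinite(q_new) && q_new >= q_old - 1e-12) break;
      fac *= 0.5;
    }
    if (!std::isfinite(q_new)) { diverged = true; break; }
    theta = theta_new;
    eta = M * theta + offset;
    if (std::abs(q_new - q_old) < tol * (std::abs(q_old) + 1.0)) {
      q_old = q_new;
      converged = true;
      break;
    }
    q_old = q_new;
  }
  if (arma::abs(theta.head(p)).max() > 1e4) diverged = true;

  arma::vec mu = arma::exp(eta);
  double lgam = 0.0;
  for (arma::uword r = 0; r < n; ++r) lgam += std::lgamma(y(r) + 1.0);
  double q_final = q_old - lgam;  // penalized objective incl. lgamma terms

  // Laplace marginal log-likelihood:
  //   cond ll - u'D^{-1}u/2 - (log det D + log det(Z'WZ + D^{-1})) / 2
  double laplace = q_final;
  if (qc + qi > 0) {
    arma::mat Huu = M.cols(p, m - 1).t() *
                    (M.cols(p, m - 1).each_col() % mu);
    Huu.diag() += pen.subvec(p, m - 1);
    double ld_huu, sign;
    arma::log_det(ld_huu, sign, Huu);
    double ld_d = 0.0;
    if (has_class) ld_d += qc * 2.0 * std::log(sigma_class);
    if (has_item) ld_d += qi * 2.0 * std::log(sigma_item);
    laplace = q_final - 0.5 * (ld_huu + ld_d);
  }

  List out = List::create(
      _["coef"] = theta, _["loglik"] = laplace,
      _["objective"] = q_final, _["fitted"] = mu,
      _["converged"] = converged && !diverged, _["diverged"] = diverged,
      _["iter"] = iter, _["n_fixed"] = (int)p,
      _["q_class"] = (int)qc, _["q_item"] = (int)qi);
  if (want_hessian) {
    arma::mat H = M.t() * (M.each_col() % mu);
    H.diag() += pen;
    out["hessian"] = H;
  }
  return out;
}
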