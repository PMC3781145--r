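// Fast logistic-regression machinery for the MB-MDR inner loop.
// Each two-locus evaluation refits 9 per-cell tests plus 2 category-level
// Wald fits; permutation p-values repeat that hundreds of times per pair,
// so the IRLS lives here rather than in stats::glm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Fit {
  arma::vec beta;
  arma::vec se;
  bool converged;
  bool separated;
};

// plain Newton/IRLS for binomial-logit; beta clamped detection of separation
static Fit irls_logistic(const arma::mat& X, const arma::vec& y,
                         int maxit = 25, double tol = 1e-9) {
  const arma::uword p = X.n_cols;
  Fit fit;
  fit.beta = arma::vec(p, arma::fill::zeros);
  fit.se = arma::vec(p, arma::fill::value(NA_REAL));
  fit.converged = false;
  fit.separated = false;

  arma::vec beta(p, arma::fill::zeros);
  // start at the null model (intercept column assumed first)
  double ybar = arma::mean(y);
  if (ybar > 0.0 && ybar < 1.0) beta(0) = std::log(ybar / (1.0 - ybar));
  arma::mat XtWX;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = arma::clamp(X * beta, -30.0, 30.0);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
    arma::vec z = eta + (y - mu) / w;
    XtWX = X.t() * (X.each_col() % w);
    arma::vec Xtwz = X.t() * (w % z);
    arma::vec bnew;
    bool ok = arma::solve(bnew, XtWX, Xtwz,
                          arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok) return fit;  // singular information: not converged
    double delta = arma::abs(bnew - beta).max();
    beta = bnew;
    if (delta < tol) { fit.converged = true; break; }
  }
  if (arma::abs(beta).max() > 15.0) fit.separated = true;

  // observed information at the final estimate
  arma::vec eta = arma::clamp(X * beta, -30.0, 30.0);
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec w = arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
  XtWX = X.t() * (X.each_col() % w);
  arma::mat cov;
  if (!arma::inv_sympd(cov, XtWX)) {
    fit.converged = false;
    return fit;
  }
  fit.beta = beta;
  fit.se = arma::sqrt(cov.diag());
  return fit;
}

// [[Rcpp::export(name = ".cpp_logistic_fit")]]
List cpp_logistic_fit(const arma::mat& X, const arma::vec& y) {
  Fit f = irls_logistic(X, y);
  return List::create(_["coef"] = f.beta, _["se"] = f.se,
                      _["converged"] = f.converged,
                      _["separated"] = f.separated);
}

// Wald z for the last column (the tested indicator) of [Xbase, ind].
// status: 0 ok, 1 not converged/singular, 2 separated, 3 degenerate indicator
static int indicator_wald(const arma::mat& Xbase, const arma::vec& ind,
                          const arma::vec& y, double& beta, double& z) {
  double s = arma::accu(ind);
  if (s < 0.5 || s > ind.n_elem - 0.5) return 3;
  arma::mat X(ind.n_elem, Xbase.n_cols + 1);
  X.cols(0, Xbase.n_cols - 1) = Xbase;
  X.col(Xbase.n_cols) = ind;
  Fit f = irls_logistic(X, y);
  if (!f.converged) return 1;
  if (f.separated) return 2;
  beta = f.beta(Xbase.n_cols);
  z = beta / f.se(Xbase.n_cols);
  return 0;
}

// One full MB-MDR evaluation of a SNP pair: per-cell tests -> H/L/O labels,
// then max(W_H, W_L). cell holds 0..8 (row-major 3*gA+gB), y holds 0/1.
// Returns W = NA when all labels are O.
static double mbmdr_eval_core(const arma::mat& Xbase, const arma::ivec& cell,
                              const arma::vec& y, double alpha_cell,
                              int min_cell, arma::ivec* labels_out,
                              arma::vec* sign_out, arma::vec* p_out,
                              arma::ivec* n_out, double* wh_out, double* wl_out) {
  const arma::uword n = cell.n_elem;
  arma::ivec labels(9, arma::fill::zeros);  // 0=O 1=H 2=L
  arma::vec psign(9, arma::fill::zeros), pval(9, arma::fill::value(NA_REAL));
  arma::ivec ncell(9, arma::fill::zeros);

  for (arma::uword i = 0; i < n; ++i) ncell(cell(i))++;

  arma::vec ind(n);
  for (int c = 0; c < 9; ++c) {
    if (ncell(c) < min_cell || ncell(c) == 0 || (arma::uword)ncell(c) == n)
      continue;
    for (arma::uword i = 0; i < n; ++i) ind(i) = (cell(i) == c) ? 1.0 : 0.0;
    double beta = 0, zz = 0;
    int st = indicator_wald(Xbase, ind, y, beta, zz);
    if (st != 0) continue;  // non-convergence or separation -> O
    double p = 2.0 * R::pnorm(-std::fabs(zz), 0.0, 1.0, 1, 0);
    psign(c) = (beta > 0) ? 1.0 : ((beta < 0) ? -1.0 : 0.0);
    pval(c) = p;
    if (p < alpha_cell && beta > 0) labels(c) = 1;
    else if (p < alpha_cell && beta < 0) labels(c) = 2;
  }

  double WH = -std::numeric_limits<double>::infinity();
  double WL = WH;
  for (int which = 1; which <= 2; ++which) {
    bool any = false;
    for (int c = 0; c < 9; ++c) if (labels(c) == which) any = true;
    if (!any) continue;
    for (arma::uword i = 0; i < n; ++i)
      ind(i) = (labels(cell(i)) == which) ? 1.0 : 0.0;
    double beta = 0, zz = 0;
    int st = indicator_wald(Xbase, ind, y, beta, zz);
    if (st != 0) continue;  // degenerate / separated component stays -Inf
    double w = zz * zz;
    if (which == 1) WH = w; else WL = w;
  }

  if (labels_out) *labels_out = labels;
  if (sign_out) *sign_out = psign;
  if (p_out) *p_out = pval;
  if (n_out) *n_out = ncell;
  if (wh_out) *wh_out = WH;
  if (wl_out) *wl_out = WL;

  double W = std::max(WH, WL);
  if (!std::isfinite(W)) return NA_REAL;
  return W;
}

// [[Rcpp::export(name = ".cpp_mbmdr_eval")]]
List cpp_mbmdr_eval(const arma::mat& Xbase, const arma::ivec& cell,
                    const arma::vec& y, double alpha_cell, int min_cell) {
  arma::ivec labels, ncell;
  arma::vec psign, pval;
  double WH, WL;
  double W = mbmdr_eval_core(Xbase, cell, y, alpha_cell, min_cell,
                             &labels, &psign, &pval, &ncell, &WH, &WL);
  return List::create(_["labels"] = labels, _["sign"] = psign,
                      _["p"] = pval, _["n_cell"] = ncell,
                      _["W"] = W, _["W_H"] = WH, _["W_L"] = WL);
}

// Recompute the full evaluation (categorization + statistic) under B
// permuted phenotypes (columns of yperm).
// [[Rcpp::export(name = ".cpp_mbmdr_perm")]]
NumericVector cpp_mbmdr_perm(const arma::mat& Xbase, const arma::ivec& cell,
                             const arma::mat& yperm, double alpha_cell,
                             int min_cell) {
  const arma::uword B = yperm.n_cols;
  NumericVector out(B);
  for (arma::uword b = 0; b < B; ++b) {
    out[b] = mbmdr_eval_core(Xbase, cell, yperm.col(b), alpha_cell, min_cell,
                             nullptr, nullptr, nullptr, nullptr, nullptr, nullptr);
  }
  return out;
}

// W for FIXED H/L sample memberships (category forcing in the replication
// stage): no re-categorization, just the two Wald fits, for each phenotype
// column of Y.
// [[Rcpp::export(name = ".cpp_fixed_w")]]
NumericVector cpp_fixed_w(const arma::mat& Xbase, const arma::vec& hind,
                          const arma::vec& lind, const arma::mat& Y,
                          bool has_h, bool has_l) {
  const arma::uword B = Y.n_cols;
  NumericVector out(B);
  for (arma::uword b = 0; b < B; ++b) {
    arma::vec y = Y.col(b);
    double WH = -std::numeric_limits<double>::infinity(), WL = WH;
    double beta, zz;
    if (has_h && indicator_wald(Xbase, hind, y, beta, zz) == 0) WH = zz * zz;
    if (has_l && indicator_wald(Xbase, lind, y, beta, zz) == 0) WL = zz * zz;
    double W = std::max(WH, WL);
    out[b] = std::isfinite(W) ? W : NA_REAL;
  }
  return out;
}
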