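// Tandem-permutation null engine for pairwise influence fits.
//
// Each permutation applies one shared row shuffle to the two tested genotype
// columns only (covariates and responses stay fixed), refits the pairwise
// interaction model per eigentrait, solves the activity changes delta,
// computes the directed influence coefficients gamma with delta-method
// standard errors, and records |gamma|/SE statistics plus recomposed
// variant-to-phenotype coefficients and variances for null averaging.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct PairEval {
  bool valid;             // fit estimable and delta solve well-conditioned
  double gamma[2];        // gamma_{1<-2}, gamma_{2<-1}
  double gamma_se[2];
  double gamma_stat[2];   // |gamma|/SE, NaN when undefined
  mat vp_coef;            // 2 x T recomposed variant-to-phenotype coefficients
  mat vp_var;             // 2 x T delta-method variances
};

// One full evaluation of the pairwise model for given (possibly permuted)
// pair columns. Zlist holds per-eigentrait covariate matrices (n x c_j,
// possibly 0 columns); the design is [1, x1, x2, x1*x2, covariates].
PairEval eval_pair(const vec& x1, const vec& x2, const mat& Y,
                   const std::vector<mat>& Zcov, const mat& W,
                   double cond_bound, double tol) {
  const uword n = Y.n_rows, k = Y.n_cols, T = W.n_cols;
  PairEval out;
  out.vp_coef.set_size(2, T); out.vp_coef.fill(datum::nan);
  out.vp_var.set_size(2, T);  out.vp_var.fill(datum::nan);
  for (int i = 0; i < 2; ++i) {
    out.gamma[i] = out.gamma_se[i] = out.gamma_stat[i] = datum::nan;
  }
  out.valid = false;

  vec x12 = x1 % x2;
  std::vector<mat> X(k), XtXinv(k);
  mat A(3, k);              // rows: beta1, beta2, beta12; cols: eigentraits
  mat resid(n, k);
  vec pj(k);
  for (uword j = 0; j < k; ++j) {
    const mat& Z = Zcov[j];
    mat Xj(n, 4 + Z.n_cols);
    Xj.col(0).ones();
    Xj.col(1) = x1; Xj.col(2) = x2; Xj.col(3) = x12;
    if (Z.n_cols > 0) Xj.cols(4, 3 + Z.n_cols) = Z;
    mat XtX = Xj.t() * Xj;
    mat inv_j;
    if (!inv_sympd(inv_j, XtX)) return out;
    vec b = inv_j * (Xj.t() * Y.col(j));
    A(0, j) = b(1); A(1, j) = b(2); A(2, j) = b(3);
    resid.col(j) = Y.col(j) - Xj * b;
    X[j] = std::move(Xj);
    XtXinv[j] = std::move(inv_j);
    pj(j) = static_cast<double>(4 + Z.n_cols);
    if (n <= 4 + Z.n_cols) return out;
  }

  // residual covariance with per-equation df normalization
  mat sigma_res(k, k);
  for (uword j = 0; j < k; ++j)
    for (uword l = 0; l < k; ++l)
      sigma_res(j, l) = dot(resid.col(j), resid.col(l)) /
        std::sqrt((n - pj(j)) * (n - pj(l)));

  // covariance of theta = (beta1_j, beta2_j, beta12_j) over eigentraits,
  // SUR cross blocks for differing designs
  mat theta_cov(3 * k, 3 * k);
  for (uword j = 0; j < k; ++j) {
    for (uword l = 0; l < k; ++l) {
      mat block;
      if (j == l) block = XtXinv[j];
      else block = XtXinv[j] * (X[j].t() * X[l]) * XtXinv[l];
      theta_cov.submat(3 * j, 3 * l, 3 * j + 2, 3 * l + 2) =
        sigma_res(j, l) * block.submat(1, 1, 3, 3);
    }
  }

  // recomposed variant-to-phenotype coefficients and variances
  for (int v = 0; v < 2; ++v) {
    rowvec a = A.row(v);                    // beta_v across eigentraits
    mat Sv(k, k);
    for (uword j = 0; j < k; ++j)
      for (uword l = 0; l < k; ++l)
        Sv(j, l) = theta_cov(3 * j + v, 3 * l + v);
    for (uword t = 0; t < T; ++t) {
      vec w = W.col(t);
      out.vp_coef(v, t) = dot(a.t(), w);
      out.vp_var(v, t) = as_scalar(w.t() * Sv * w);
    }
  }

  // activity-change solve: B delta = beta12 (exact for k = 2, LS otherwise)
  mat B(k, 2);
  B.col(0) = A.row(0).t(); B.col(1) = A.row(1).t();
  vec cvec = A.row(2).t();
  vec sv = svd(B);
  if (sv(1) <= 0 || sv(0) / sv(1) > cond_bound) return out;
  mat Minv = inv_sympd(B.t() * B);
  vec delta = Minv * (B.t() * cvec);
  vec r = cvec - B * delta;

  // Jacobian of delta wrt theta
  mat grad(2, 3 * k, fill::zeros);
  for (uword j = 0; j < k; ++j) {
    vec Bj = B.row(j).t();
    for (int m = 0; m < 2; ++m) {
      vec em(2, fill::zeros); em(m) = 1.0;
      grad.col(3 * j + m) = Minv * (em * r(j) - delta(m) * Bj);
    }
    grad.col(3 * j + 2) = Minv * Bj;
  }

  double den[2] = {1.0 + delta(1), 1.0 + delta(0)};
  mat J(2, 2, fill::zeros);
  bool defined[2];
  for (int i = 0; i < 2; ++i) defined[i] = std::abs(den[i]) >= tol;
  if (defined[0]) { J(0, 0) = 1.0 / den[0]; J(0, 1) = -delta(0) / (den[0] * den[0]); }
  if (defined[1]) { J(1, 0) = -delta(1) / (den[1] * den[1]); J(1, 1) = 1.0 / den[1]; }
  mat Gg = J * grad;
  mat gcov = Gg * theta_cov * Gg.t();
  double gval[2] = {defined[0] ? delta(0) / den[0] : datum::nan,
                    defined[1] ? delta(1) / den[1] : datum::nan};
  for (int i = 0; i < 2; ++i) {
    if (!defined[i]) continue;
    double v = std::max(gcov(i, i), 0.0);
    out.gamma[i] = gval[i];
    out.gamma_se[i] = std::sqrt(v);
    out.gamma_stat[i] = v > 0 ? std::abs(gval[i]) / std::sqrt(v) : datum::nan;
  }
  out.valid = true;
  return out;
}

std::vector<mat> as_zcov(const Rcpp::List& Zlist, uword n) {
  std::vector<mat> Z(Zlist.size());
  for (int j = 0; j < Zlist.size(); ++j) {
    Rcpp::NumericMatrix zj(Zlist[j]);
    Z[j] = mat(zj.begin(), zj.nrow(), zj.ncol());
    if (Z[j].n_cols > 0 && Z[j].n_rows != n)
      Rcpp::stop("covariate matrix row count mismatch");
  }
  return Z;
}

}  // namespace

//' One pairwise-model evaluation (compiled path)
//'
//' Internal: evaluates the pairwise interaction model, activity-change
//' solve, and influence coefficients exactly as the permutation engine
//' does, for cross-checking against the reference R implementation.
//'
//' @keywords internal
// [[Rcpp::export(name = ".pair_eval_cpp")]]
Rcpp::List pair_eval_cpp(const arma::vec& x1, const arma::vec& x2,
                         const arma::mat& Y, const Rcpp::List& Zlist,
                         const arma::mat& W,
                         double cond_bound = 1e8, double tol = 1e-8) {
  std::vector<mat> Z = as_zcov(Zlist, Y.n_rows);
  PairEval e = eval_pair(x1, x2, Y, Z, W, cond_bound, tol);
  return Rcpp::List::create(
    Rcpp::Named("valid") = e.valid,
    Rcpp::Named("gamma") = Rcpp::NumericVector::create(e.gamma[0], e.gamma[1]),
    Rcpp::Named("gamma_se") = Rcpp::NumericVector::create(e.gamma_se[0], e.gamma_se[1]),
    Rcpp::Named("gamma_stat") = Rcpp::NumericVector::create(e.gamma_stat[0], e.gamma_stat[1]),
    Rcpp::Named("vp_coef") = e.vp_coef,
    Rcpp::Named("vp_var") = e.vp_var);
}

//' Tandem-permutation null distributions (compiled path)
//'
//' Internal: applies `n_perm` shared row shuffles to the two pair columns,
//' re-evaluates the full pipeline per permutation, and collects influence
//' statistics and recomposed variant-to-phenotype coefficients/variances.
//' The RNG is a self-seeded mt19937_64 Fisher-Yates so results depend only
//' on `seed`.
//'
//' @keywords internal
// [[Rcpp::export(name = ".tandem_perm_null_cpp")]]
Rcpp::List tandem_perm_null_cpp(const arma::vec& x1, const arma::vec& x2,
                                const arma::mat& Y, const Rcpp::List& Zlist,
                                const arma::mat& W, int n_perm,
                                double seed,
                                double cond_bound = 1e8, double tol = 1e-8) {
  if (n_perm < 1) Rcpp::stop("n_perm must be >= 1");
  const uword n = Y.n_rows, T = W.n_cols;
  std::vector<mat> Z = as_zcov(Zlist, n);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  mat gamma_stat(n_perm, 2); gamma_stat.fill(datum::nan);
  mat gamma_val(n_perm, 2);  gamma_val.fill(datum::nan);
  mat vp_coef(n_perm, 2 * T); vp_coef.fill(datum::nan);
  mat vp_var(n_perm, 2 * T);  vp_var.fill(datum::nan);
  Rcpp::LogicalVector valid(n_perm);

  std::vector<uword> idx(n);
  vec x1p(n), x2p(n);
  for (int b = 0; b < n_perm; ++b) {
    for (uword i = 0; i < n; ++i) idx[i] = i;
    for (uword i = n - 1; i > 0; --i) {
      uword j = static_cast<uword>(rng() % (i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (uword i = 0; i < n; ++i) { x1p(i) = x1(idx[i]); x2p(i) = x2(idx[i]); }
    PairEval e = eval_pair(x1p, x2p, Y, Z, W, cond_bound, tol);
    valid[b] = e.valid;
    if (!e.valid) continue;
    gamma_stat(b, 0) = e.gamma_stat[0]; gamma_stat(b, 1) = e.gamma_stat[1];
    gamma_val(b, 0) = e.gamma[0];       gamma_val(b, 1) = e.gamma[1];
    for (int v = 0; v < 2; ++v)
      for (uword t = 0; t < T; ++t) {
        vp_coef(b, v * T + t) = e.vp_coef(v, t);
        vp_var(b, v * T + t) = e.vp_var(v, t);
      }
  }
  return Rcpp::List::create(
    Rcpp::Named("gamma_stat") = gamma_stat,
    Rcpp::Named("gamma") = gamma_val,
    Rcpp::Named("vp_coef") = vp_coef,
    Rcpp::Named("vp_var") = vp_var,
    Rcpp::Named("valid") = valid);
}
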