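// PLS1 (single-response partial least squares) via the NIPALS recursion,
// plus a k-fold cross-validated RMSE used by the random-frog subset search.
// Kept in C++ because subset-search selectors refit PLS thousands of times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core NIPALS on column-centered X and centered y. Returns the regression
// vector in the original (uncentered) coordinates: [intercept, beta_1..p].
static vec pls1_nipals(const mat& X, const vec& y, int ncomp) {
  const uword n = X.n_rows, p = X.n_cols;
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;

  int A = std::min<int>(ncomp, std::min<uword>(n > 0 ? n - 1 : 0, p));
  if (A < 0) A = 0;
  mat W(p, A, fill::zeros), P(p, A, fill::zeros);
  vec q(A, fill::zeros);

  int a = 0;
  for (; a < A; ++a) {
    vec w = Xc.t() * yc;
    double nw = norm(w);
    if (nw < 1e-12) break;        // y residual orthogonal to X: stop
    w /= nw;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < 1e-24) break;        // degenerate score
    vec pl = Xc.t() * t / tt;
    double qa = dot(yc, t) / tt;
    Xc -= t * pl.t();
    yc -= qa * t;
    W.col(a) = w;
    P.col(a) = pl;
    q(a) = qa;
  }

  vec out(p + 1, fill::zeros);
  if (a == 0) {                   // intercept-only model
    out(0) = ym;
    return out;
  }
  mat Wa = W.cols(0, a - 1), Pa = P.cols(0, a - 1);
  vec qa = q.subvec(0, a - 1);
  vec beta = Wa * solve(Pa.t() * Wa, qa);
  out(0) = ym - dot(xm, beta);
  out.subvec(1, p) = beta;
  return out;
}

// [[Rcpp::export]]
arma::vec pls1_coef_cpp(const arma::mat& X, const arma::vec& y, int ncomp) {
  if (X.n_rows != y.n_elem)
    Rcpp::stop("X and y dimensions disagree");
  return pls1_nipals(X, y, ncomp);
}

// k-fold CV RMSE. fold_id carries integers 1..k assigning each row to a fold;
// the latent count is clamped per fold to min(ncomp, n_train - 1, p).
// [[Rcpp::export]]
double pls1_cv_rmse_cpp(const arma::mat& X, const arma::vec& y, int ncomp,
                        const arma::ivec& fold_id) {
  const uword n = X.n_rows;
  if (fold_id.n_elem != n || y.n_elem != n)
    Rcpp::stop("fold_id/y length must match rows of X");
  int k = fold_id.max();
  double sse = 0.0;
  uword m = 0;
  for (int f = 1; f <= k; ++f) {
    uvec test = find(fold_id == f);
    if (test.n_elem == 0) continue;
    uvec train = find(fold_id != f);
    if (train.n_elem < 2) Rcpp::stop("fold leaves fewer than 2 training rows");
    vec cf = pls1_nipals(X.rows(train), y.elem(train), ncomp);
    vec pred = X.rows(test) * cf.subvec(1, X.n_cols) + cf(0);
    vec resid = pred - y.elem(test);
    sse += dot(resid, resid);
    m += test.n_elem;
  }
  if (m == 0) Rcpp::stop("no test observations across folds");
  return std::sqrt(sse / m);
}
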