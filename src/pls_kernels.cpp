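// NIPALS PLS1 and cross-validated prediction error, used by the R-level
// fitting, RMSECV, backward-elimination and annealing code. Single-response
// NIPALS needs no inner iteration: each component is obtained in closed form
// and the predictor matrix is deflated.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core PLS1 decomposition on pre-centered data. Fills W (weights), P (x
// loadings), q (y loadings), T (scores). Returns the number of components
// actually extracted (< n_lv when X deflates to numerical zero).
static int nipals_pls1(const mat& Xc, const vec& yc, int n_lv,
                       mat& W, mat& P, vec& q, mat& T) {
  mat X = Xc;
  vec y = yc;
  const double x0 = norm(X, "fro");
  const double tol = 1e-12 * (x0 > 0 ? x0 : 1.0);
  int a = 0;
  for (; a < n_lv; ++a) {
    vec w = X.t() * y;
    double wn = norm(w);
    if (wn < tol) break;
    w /= wn;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < tol * tol) break;
    vec p = X.t() * t / tt;
    double qa = dot(y, t) / tt;
    W.col(a) = w;
    P.col(a) = p;
    q(a) = qa;
    T.col(a) = t;
    X -= t * p.t();
    y -= qa * t;
  }
  return a;
}

// Regression coefficients for every component count 1..n_used:
// B_a = W_a (P_a' W_a)^{-1} q_a. Columns beyond n_used repeat the last
// valid column (model cannot improve once X is exhausted).
static mat pls1_coefs(const mat& W, const mat& P, const vec& q,
                      int n_used, int n_lv) {
  const uword m = W.n_rows;
  mat B(m, n_lv, fill::zeros);
  for (int a = 1; a <= n_used; ++a) {
    mat Wa = W.cols(0, a - 1);
    mat Pa = P.cols(0, a - 1);
    vec qa = q.subvec(0, a - 1);
    vec b = Wa * solve(Pa.t() * Wa, qa);
    B.col(a - 1) = b;
  }
  for (int a = n_used; a < n_lv; ++a) {
    B.col(a) = (n_used > 0) ? B.col(n_used - 1) : vec(m, fill::zeros);
  }
  return B;
}

// [[Rcpp::export]]
Rcpp::List cpp_pls_fit(const arma::mat& X, const arma::vec& y, int n_lv) {
  const uword n = X.n_rows, m = X.n_cols;
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat W(m, n_lv, fill::zeros), P(m, n_lv, fill::zeros), T(n, n_lv, fill::zeros);
  vec q(n_lv, fill::zeros);
  int used = nipals_pls1(Xc, yc, n_lv, W, P, q, T);
  mat B = pls1_coefs(W, P, q, used, n_lv);
  return Rcpp::List::create(
    Rcpp::Named("x_mean") = xm.t(),
    Rcpp::Named("y_mean") = ym,
    Rcpp::Named("weights") = W.cols(0, std::max(used, 1) - 1),
    Rcpp::Named("x_loadings") = P.cols(0, std::max(used, 1) - 1),
    Rcpp::Named("y_loadings") = q.subvec(0, std::max(used, 1) - 1),
    Rcpp::Named("scores") = T.cols(0, std::max(used, 1) - 1),
    Rcpp::Named("coefficients") = B,
    Rcpp::Named("n_extracted") = used);
}

// Cross-validated RMSE for component counts 1..max_lv. fold_id is 1-based;
// leave-one-out corresponds to fold_id = 1..n.
// [[Rcpp::export]]
arma::vec cpp_press(const arma::mat& X, const arma::vec& y,
                    const arma::ivec& fold_id, int max_lv) {
  const uword n = X.n_rows, m = X.n_cols;
  const int K = fold_id.max();
  vec sse(max_lv, fill::zeros);
  for (int kfold = 1; kfold <= K; ++kfold) {
    uvec test = find(fold_id == kfold);
    uvec train = find(fold_id != kfold);
    mat Xt = X.rows(train);
    vec yt = y.elem(train);
    rowvec xm = mean(Xt, 0);
    double ym = mean(yt);
    mat Xc = Xt.each_row() - xm;
    vec yc = yt - ym;
    mat W(m, max_lv, fill::zeros), P(m, max_lv, fill::zeros);
    mat T(train.n_elem, max_lv, fill::zeros);
    vec q(max_lv, fill::zeros);
    int used = nipals_pls1(Xc, yc, max_lv, W, P, q, T);
    mat B = pls1_coefs(W, P, q, used, max_lv);
    mat Xv = X.rows(test);
    Xv.each_row() -= xm;
    mat pred = Xv * B;           // test x max_lv
    pred += ym;
    for (int a = 0; a < max_lv; ++a) {
      vec e = pred.col(a) - y.elem(test);
      sse(a) += dot(e, e);
    }
  }
  return sqrt(sse / double(n));
}
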