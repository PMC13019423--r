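// NIPALS PLS2 core with X-only deflation, plus leave-one-out and
// label-permutation loops. The NIPALS inner power iteration for the weight
// vector is solved at its fixed point: w is the dominant left singular
// vector of Z = Xd' Yc, obtained from the g x g eigenproblem of Z' Z, which
// is exact and deterministic (no iteration-count sensitivity).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct PlsFit {
  mat W, P, Q, T;   // p x A, p x A, g x A, n x A
  rowvec x_mean, y_mean;
  vec ssy;          // Y-variance captured per component: tt * ||q||^2
  int A;            // components actually extracted
};

static PlsFit nipals_fit(const mat& X, const mat& Y, int A) {
  const int n = X.n_rows, p = X.n_cols, g = Y.n_cols;
  PlsFit f;
  f.x_mean = mean(X, 0);
  f.y_mean = mean(Y, 0);
  mat Xd = X.each_row() - f.x_mean;
  mat Yc = Y.each_row() - f.y_mean;
  const double x_scale = accu(square(Xd));
  f.W.set_size(p, A); f.P.set_size(p, A); f.Q.set_size(g, A);
  f.T.set_size(n, A); f.ssy.set_size(A);
  int a = 0;
  for (; a < A; ++a) {
    mat Z = Xd.t() * Yc;                 // p x g
    mat C = Z.t() * Z;                   // g x g
    vec eigval; mat eigvec;
    if (!eig_sym(eigval, eigvec, C)) break;
    vec q0 = eigvec.col(g - 1);
    vec w = Z * q0;
    double wn = norm(w);
    if (wn < 1e-14 * (1.0 + x_scale)) break;
    w /= wn;
    vec t = Xd * w;
    double tt = dot(t, t);
    if (tt < 1e-12 * (1.0 + x_scale / n)) break;
    vec pl = Xd.t() * t / tt;
    vec ql = Yc.t() * t / tt;
    // sign convention: largest-|.| element of w positive
    uword j = index_max(abs(w));
    if (w(j) < 0) { w = -w; t = -t; pl = -pl; ql = -ql; }
    Xd -= t * pl.t();
    f.W.col(a) = w; f.P.col(a) = pl; f.Q.col(a) = ql; f.T.col(a) = t;
    f.ssy(a) = tt * dot(ql, ql);
  }
  f.A = a;
  if (a < A) {
    f.W = f.W.head_cols(std::max(a, 1));
    f.P = f.P.head_cols(std::max(a, 1));
    f.Q = f.Q.head_cols(std::max(a, 1));
    f.T = f.T.head_cols(std::max(a, 1));
    f.ssy = f.ssy.head(std::max(a, 1));
  }
  return f;
}

// regression coefficients for the first A components
static mat pls_coef(const PlsFit& f, int A) {
  mat Wa = f.W.head_cols(A), Pa = f.P.head_cols(A), Qa = f.Q.head_cols(A);
  return Wa * solve(Pa.t() * Wa, Qa.t());   // p x g
}

// [[Rcpp::export]]
Rcpp::List cpp_pls_fit(const arma::mat& X, const arma::mat& Y, int A) {
  PlsFit f = nipals_fit(X, Y, A);
  mat B = pls_coef(f, f.A);
  return Rcpp::List::create(
    Rcpp::Named("x_weights") = f.W,
    Rcpp::Named("x_loadings") = f.P,
    Rcpp::Named("y_loadings") = f.Q,
    Rcpp::Named("x_scores") = f.T,
    Rcpp::Named("coefficients") = B,
    Rcpp::Named("x_mean") = f.x_mean,
    Rcpp::Named("y_mean") = f.y_mean,
    Rcpp::Named("ssy") = f.ssy,
    Rcpp::Named("n_components") = f.A);
}

// sequential per-component prediction of one row; fills yhat for A = 1..Amax
static void predict_path(const PlsFit& f, const rowvec& x, mat& yhat_path) {
  const int g = f.Q.n_rows;
  rowvec xd = x - f.x_mean;
  rowvec acc = f.y_mean;
  for (int a = 0; a < (int)yhat_path.n_rows; ++a) {
    if (a < f.A) {
      double t = dot(xd, f.W.col(a));
      xd -= t * f.P.col(a).t();
      acc += t * f.Q.col(a).t();
    }
    for (int k = 0; k < g; ++k) yhat_path(a, k) = acc(k);
  }
}

// LOO over A = 1..Amax: accuracy and PRESS per A
static void loo_core(const mat& X, const uvec& cls, int g, int Amax,
                     vec& acc, vec& press) {
  const int n = X.n_rows;
  mat Y(n, g, fill::zeros);
  for (int i = 0; i < n; ++i) Y(i, cls(i)) = 1.0;
  acc.zeros(Amax); press.zeros(Amax);
  mat yhat_path(Amax, g);
  for (int i = 0; i < n; ++i) {
    uvec keep = regspace<uvec>(0, n - 1);
    keep.shed_row(i);
    PlsFit f = nipals_fit(X.rows(keep), Y.rows(keep), Amax);
    predict_path(f, X.row(i), yhat_path);
    for (int a = 0; a < Amax; ++a) {
      uword pred = index_max(yhat_path.row(a));
      if ((int)pred == (int)cls(i)) acc(a) += 1.0;
      press(a) += accu(square(Y.row(i) - yhat_path.row(a)));
    }
  }
  acc /= n;
}

// [[Rcpp::export]]
Rcpp::List cpp_pls_loo(const arma::mat& X, const arma::ivec& cls0, int g,
                       int Amax) {
  uvec cls = conv_to<uvec>::from(cls0);
  vec acc, press;
  loo_core(X, cls, g, Amax, acc, press);
  return Rcpp::List::create(Rcpp::Named("accuracy") = acc,
                            Rcpp::Named("press") = press);
}

// max-over-A LOO accuracy for each permuted label column
// [[Rcpp::export]]
arma::vec cpp_perm_acc(const arma::mat& X, const arma::imat& perms, int g,
                       int Amax) {
  const int n_perm = perms.n_cols;
  vec out(n_perm);
  vec acc, press;
  for (int j = 0; j < n_perm; ++j) {
    uvec cls = conv_to<uvec>::from(ivec(perms.col(j)));
    loo_core(X, cls, g, Amax, acc, press);
    out(j) = acc.max();
  }
  return out;
}
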