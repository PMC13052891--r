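// Layer primitives for the convolutional sequence classifier.
// Activations are column-major arrays (channels x width x batch); the
// convolution is one BLAS dgemm over an im2col unfolding. Outputs are
// written straight into R-allocated vectors (no intermediate copies),
// and backward passes rebuild cheap intermediates (im2col, xhat) from
// the cached layer inputs instead of shuttling them through R.
// Everything is double precision and single-threaded, so results are
// bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

static cube view_cube(NumericVector x) {
  IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

static NumericVector alloc_arr(int d1, int d2, int d3) {
  NumericVector out(no_init((R_xlen_t)d1 * d2 * d3));
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  return out;
}

static void im2col_fill(const cube& X, int K, mat& Xcol) {
  const int C = X.n_rows, W = X.n_cols, B = X.n_slices, Wp = W - K + 1;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < Wp; ++j) {
      double* dst = Xcol.colptr((uword)b * Wp + j);
      for (int k = 0; k < K; ++k) {
        std::memcpy(dst + (uword)k * C, X.slice_colptr(b, j + k),
                    C * sizeof(double));
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector X_, NumericVector W_,
                           NumericVector b_) {
  cube X = view_cube(X_);
  IntegerVector wd = W_.attr("dim"); // out x C x K
  const int out = wd[0], C = wd[1], K = wd[2];
  const int W = X.n_cols, B = X.n_slices, Wp = W - K + 1;
  mat Wmat(W_.begin(), out, (uword)C * K, false, true);
  mat Xcol((uword)C * K, (uword)Wp * B);
  im2col_fill(X, K, Xcol);

  NumericVector Yv = alloc_arr(out, Wp, B);
  mat Y(Yv.begin(), out, (uword)Wp * B, false, true);
  Y = Wmat * Xcol;
  vec bb(b_.begin(), out, false, true);
  Y.each_col() += bb;
  return Yv;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector W_, NumericVector X_, NumericVector dY_) {
  cube X = view_cube(X_);
  IntegerVector wd = W_.attr("dim");
  const int out = wd[0], C = wd[1], K = wd[2];
  const int W = X.n_cols, B = X.n_slices, Wp = W - K + 1;
  mat Wmat(W_.begin(), out, (uword)C * K, false, true);
  mat dYm(dY_.begin(), out, (uword)Wp * B, false, true);

  mat Xcol((uword)C * K, (uword)Wp * B);
  im2col_fill(X, K, Xcol);

  NumericVector dWv(no_init(W_.size()));
  dWv.attr("dim") = wd;
  mat dW(dWv.begin(), out, (uword)C * K, false, true);
  dW = dYm * Xcol.t();
  vec db = arma::sum(dYm, 1);
  mat dXcol = Wmat.t() * dYm;

  NumericVector dXv = alloc_arr(C, W, B);
  cube dX(dXv.begin(), C, W, B, false, true);
  dX.zeros();
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < Wp; ++j) {
      const double* src = dXcol.colptr((uword)b * Wp + j);
      for (int k = 0; k < K; ++k) {
        double* dst = dX.slice_colptr(b, j + k);
        const double* s = src + (uword)k * C;
        for (int c = 0; c < C; ++c) dst[c] += s[c];
      }
    }
  }
  return List::create(_["dX"] = dXv, _["dW"] = dWv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector X_, NumericVector gamma_, NumericVector beta_,
                NumericVector rmean_, NumericVector rvar_, bool training,
                double eps) {
  IntegerVector d = X_.attr("dim");
  const int C = d[0];
  const uword M = (uword)d[1] * d[2];
  mat X(X_.begin(), C, M, false, true);
  vec g(gamma_.begin(), C, false, true), bt(beta_.begin(), C, false, true);

  NumericVector Yv = alloc_arr(d[0], d[1], d[2]);
  mat Y(Yv.begin(), C, M, false, true);

  vec mu(C), v(C), invstd(C);
  if (training) {
    mu = arma::mean(X, 1);
    Y = X.each_col() - mu;
    v = arma::mean(arma::square(Y), 1);
    invstd = 1.0 / arma::sqrt(v + eps);
  } else {
    mu = vec(rmean_.begin(), C);
    v = vec(rvar_.begin(), C);
    invstd = 1.0 / arma::sqrt(v + eps);
    Y = X.each_col() - mu;
  }
  Y.each_col() %= (g % invstd);
  Y.each_col() += bt;
  return List::create(
    _["Y"] = Yv,
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["invstd"] = NumericVector(invstd.begin(), invstd.end()));
}

// training-mode backward; xhat is recomputed from the cached layer input
// [[Rcpp::export]]
List cpp_bn_bwd_train(NumericVector dY_, NumericVector X_, NumericVector mu_,
                      NumericVector invstd_, NumericVector gamma_) {
  IntegerVector d = dY_.attr("dim");
  const int C = d[0];
  const uword M = (uword)d[1] * d[2];
  mat dY(dY_.begin(), C, M, false, true);
  mat X(X_.begin(), C, M, false, true);
  vec mu(mu_.begin(), C, false, true);
  vec invstd(invstd_.begin(), C, false, true);
  vec g(gamma_.begin(), C, false, true);

  mat xhat = X.each_col() - mu;
  xhat.each_col() %= invstd;

  vec dgamma = arma::sum(dY % xhat, 1);
  vec dbeta = arma::sum(dY, 1);

  NumericVector dXv = alloc_arr(d[0], d[1], d[2]);
  mat dX(dXv.begin(), C, M, false, true);
  // dX = invstd/M * (M*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat)),
  // with dxhat = dY * gamma
  vec s1 = g % dbeta;                 // sum of dxhat
  vec s2 = g % dgamma;                // sum of dxhat * xhat
  dX = dY.each_col() % (g * (double)M);
  dX.each_col() -= s1;
  dX -= xhat.each_col() % s2;
  dX.each_col() %= (invstd / (double)M);
  return List::create(
    _["dX"] = dXv,
    _["dgamma"] = NumericVector(dgamma.begin(), dgamma.end()),
    _["dbeta"] = NumericVector(dbeta.begin(), dbeta.end()));
}

// [[Rcpp::export]]
NumericVector cpp_bn_bwd_infer(NumericVector dY_, NumericVector invstd_,
                               NumericVector gamma_) {
  IntegerVector d = dY_.attr("dim");
  const int C = d[0];
  const uword M = (uword)d[1] * d[2];
  mat dY(dY_.begin(), C, M, false, true);
  vec invstd(invstd_.begin(), C, false, true);
  vec g(gamma_.begin(), C, false, true);
  NumericVector dXv = alloc_arr(d[0], d[1], d[2]);
  mat dX(dXv.begin(), C, M, false, true);
  dX = dY.each_col() % (g % invstd);
  return dXv;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector X_) {
  NumericVector Y(no_init(X_.size()));
  Y.attr("dim") = X_.attr("dim");
  const double* x = X_.begin();
  double* y = Y.begin();
  const R_xlen_t n = X_.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return Y;
}

// gradient through ReLU, using the forward output (Y > 0 iff input > 0)
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dY_, NumericVector Y_) {
  NumericVector dX(no_init(dY_.size()));
  dX.attr("dim") = dY_.attr("dim");
  const double* dy = dY_.begin();
  const double* y = Y_.begin();
  double* dx = dX.begin();
  const R_xlen_t n = dY_.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  return dX;
}

// width-2 max pooling; ties route the gradient to the left element
// [[Rcpp::export]]
List cpp_pool2_fwd(NumericVector X_) {
  cube X = view_cube(X_);
  const int C = X.n_rows, W = X.n_cols, B = X.n_slices, W2 = W / 2;
  NumericVector Yv = alloc_arr(C, W2, B);
  cube Y(Yv.begin(), C, W2, B, false, true);
  LogicalVector left(no_init((R_xlen_t)C * W2 * B));
  R_xlen_t q = 0;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < W2; ++j) {
      const double* x1 = X.slice_colptr(b, 2 * j);
      const double* x2 = X.slice_colptr(b, 2 * j + 1);
      double* y = Y.slice_colptr(b, j);
      for (int c = 0; c < C; ++c, ++q) {
        const bool l = x1[c] >= x2[c];
        left[q] = l;
        y[c] = l ? x1[c] : x2[c];
      }
    }
  }
  return List::create(_["Y"] = Yv, _["left"] = left,
                      _["in_dim"] = IntegerVector::create(C, W, B));
}

// [[Rcpp::export]]
NumericVector cpp_pool2_bwd(NumericVector dY_, LogicalVector left,
                            IntegerVector in_dim) {
  cube dY = view_cube(dY_);
  const int C = in_dim[0], W = in_dim[1], B = in_dim[2], W2 = dY.n_cols;
  NumericVector dXv = alloc_arr(C, W, B);
  cube dX(dXv.begin(), C, W, B, false, true);
  dX.zeros();
  R_xlen_t q = 0;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < W2; ++j) {
      const double* g = dY.slice_colptr(b, j);
      double* d1 = dX.slice_colptr(b, 2 * j);
      double* d2 = dX.slice_colptr(b, 2 * j + 1);
      for (int c = 0; c < C; ++c, ++q) {
        if (left[q]) d1[c] = g[c]; else d2[c] = g[c];
      }
    }
  }
  return dXv;
}
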