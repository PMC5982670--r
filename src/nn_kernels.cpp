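// Compiled kernels for the 1-D convolutional network engine.
//
// A minibatch of B windows (C channels x L samples) is laid out as a
// C x (L*B) matrix with per-window column blocks. The kernels below do the
// data movement (im2col, col2im scatter, 1x2 max-pooling) that dominates a
// plain-R implementation; the matrix products stay in BLAS via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for a kernel-3 "same" convolution: rows are the [left; centre;
// right] shifted copies, zero-padded at window boundaries.
static arma::mat buildZ(const arma::mat& X, const int L) {
  const int C = X.n_rows, LB = X.n_cols, B = LB / L;
  arma::mat Z(3 * C, LB, arma::fill::zeros);
  Z.rows(C, 2 * C - 1) = X;
  for (int s = 0; s < B; ++s) {
    const int off = s * L;
    Z.submat(0, off + 1, C - 1, off + L - 1) = X.cols(off, off + L - 2);
    Z.submat(2 * C, off, 3 * C - 1, off + L - 2) =
        X.cols(off + 1, off + L - 1);
  }
  return Z;
}

// [[Rcpp::export(name = ".conv1dFwd")]]
arma::mat conv1dFwd(const arma::mat& X, const arma::mat& W,
                    const arma::vec& b, const int L) {
  arma::mat Y = W * buildZ(X, L);
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export(name = ".conv1dBwd")]]
Rcpp::List conv1dBwd(const arma::mat& X, const arma::mat& W,
                     const arma::mat& dY, const int L) {
  const int C = X.n_rows, LB = X.n_cols, B = LB / L;
  arma::mat Z = buildZ(X, L);
  arma::mat dW = dY * Z.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dZ = W.t() * dY;
  arma::mat dX = dZ.rows(C, 2 * C - 1);
  for (int s = 0; s < B; ++s) {
    const int off = s * L;
    dX.cols(off, off + L - 2) +=
        dZ.submat(0, off + 1, C - 1, off + L - 1);
    dX.cols(off + 1, off + L - 1) +=
        dZ.submat(2 * C, off, 3 * C - 1, off + L - 2);
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// 1x2 max-pooling, stride 2. L is even, so pooling pairs never straddle a
// window boundary. Ties keep the first (left) element.
// [[Rcpp::export(name = ".poolFwd")]]
Rcpp::List poolFwd(const arma::mat& X) {
  const int C = X.n_rows, half = X.n_cols / 2;
  arma::mat Y(C, half);
  arma::umat takeFirst(C, half);
  for (int j = 0; j < half; ++j) {
    for (int i = 0; i < C; ++i) {
      const double a = X(i, 2 * j), b = X(i, 2 * j + 1);
      const bool f = a >= b;
      takeFirst(i, j) = f;
      Y(i, j) = f ? a : b;
    }
  }
  return List::create(_["Y"] = Y, _["takeFirst"] = takeFirst);
}

// [[Rcpp::export(name = ".poolBwd")]]
arma::mat poolBwd(const arma::mat& dY, const arma::umat& takeFirst) {
  const int C = dY.n_rows, half = dY.n_cols;
  arma::mat dX(C, 2 * half, arma::fill::zeros);
  for (int j = 0; j < half; ++j)
    for (int i = 0; i < C; ++i)
      dX(i, 2 * j + (takeFirst(i, j) ? 0 : 1)) = dY(i, j);
  return dX;
}
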