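// 1-D convolution kernels for the GAN converter (im2col + GEMM).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// X: T x Cin.  Returns (Tout x K*Cin) patch matrix; column order is
// (tap 1 ch 1, tap 2 ch 1, ..., tap K ch 1, tap 1 ch 2, ...).
static arma::mat im2col1d(const arma::mat& X, int K, int padl, int padr) {
  const int T = X.n_rows, Cin = X.n_cols;
  const int Tout = T + padl + padr - K + 1;
  arma::mat P(Tout, K * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int k = 0; k < K; ++k) {
      // output row t reads input row t - padl + k
      const int lo = std::max(0, padl - k);
      const int hi = std::min(Tout - 1, T - 1 + padl - k);
      if (hi < lo) continue;
      P.submat(lo, c * K + k, hi, c * K + k) =
        X.submat(lo - padl + k, c, hi - padl + k, c);
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, const arma::mat& W,
                         const arma::rowvec& b, int K, int padl, int padr) {
  arma::mat Y = im2col1d(X, K, padl, padr) * W;
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::mat& X, const arma::mat& W,
                    const arma::mat& dY, int K, int padl, int padr) {
  const int T = X.n_rows, Cin = X.n_cols;
  const int Tout = dY.n_rows;
  arma::mat P = im2col1d(X, K, padl, padr);
  arma::mat dW = P.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  // dX via col2im of dY * W'
  arma::mat dP = dY * W.t();
  arma::mat dX(T, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int k = 0; k < K; ++k) {
      const int lo = std::max(0, padl - k);
      const int hi = std::min(Tout - 1, T - 1 + padl - k);
      if (hi < lo) continue;
      dX.submat(lo - padl + k, c, hi - padl + k, c) +=
        dP.submat(lo, c * K + k, hi, c * K + k);
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Batched variants: slices of the cubes are individual windows (T x Cin).
// [[Rcpp::export]]
arma::cube conv1d_fwd_batch_cpp(const arma::cube& X, const arma::mat& W,
                                const arma::rowvec& b, int K, int padl,
                                int padr) {
  const int n = X.n_slices;
  const int Tout = X.n_rows + padl + padr - K + 1;
  arma::cube Y(Tout, W.n_cols, n);
  for (int s = 0; s < n; ++s) {
    arma::mat y = im2col1d(X.slice(s), K, padl, padr) * W;
    y.each_row() += b;
    Y.slice(s) = y;
  }
  return Y;
}

// [[Rcpp::export]]
List conv1d_bwd_batch_cpp(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, int K, int padl, int padr) {
  const int n = X.n_slices;
  const int T = X.n_rows, Cin = X.n_cols, Tout = dY.n_rows;
  arma::cube dX(T, Cin, n, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::rowvec db(W.n_cols, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    arma::mat P = im2col1d(X.slice(s), K, padl, padr);
    dW += P.t() * dY.slice(s);
    db += arma::sum(dY.slice(s), 0);
    arma::mat dP = dY.slice(s) * W.t();
    arma::mat dXs(T, Cin, arma::fill::zeros);
    for (int c = 0; c < Cin; ++c) {
      for (int k = 0; k < K; ++k) {
        const int lo = std::max(0, padl - k);
        const int hi = std::min(Tout - 1, T - 1 + padl - k);
        if (hi < lo) continue;
        dXs.submat(lo - padl + k, c, hi - padl + k, c) +=
          dP.submat(lo, c * K + k, hi, c * K + k);
      }
    }
    dX.slice(s) = dXs;
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
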