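// Minimal convolutional primitives for the residual-learning localizers:
// im2col/col2im plus forward/backward 'same' convolutions as BLAS matrix
// products. Single-sample cubes (H x W x C); stride-1 kernels; the x3
// transposed convolution is composed in R from zero-stuffing + conv.
// Internals run in single precision (the optimizer noise floor is far
// above float epsilon) with a (H*W) x (C*k*k) column layout so that both
// the im2col writes and the GEMMs are memory-contiguous. The column
// matrices never cross the R boundary: the backward pass recomputes
// im2col from the cached layer input.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static fcube as_f(const cube& x) { return conv_to<fcube>::from(x); }
static fmat as_f(const mat& x) { return conv_to<fmat>::from(x); }

// columns layout: colT(j*H + i, c*k*k + dj*k + di) = x(i+di-p, j+dj-p, c)
static fmat im2colT_(const fcube& x, const int k, const int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat colT(H * W, C * k * k, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
        const int j0 = std::max(0, p - dj), j1 = std::min(W, W + p - dj);
        float* colbase = colT.colptr(r);
        for (int j = j0; j < j1; ++j) {
          const float* src = &x(i0 + di - p, j + dj - p, c);
          float* dst = colbase + j * H + i0;
          std::memcpy(dst, src, sizeof(float) * (i1 - i0));
        }
      }
    }
  }
  return colT;
}

static fcube col2imT_(const fmat& colT, const int H, const int W,
                      const int C, const int k, const int p) {
  fcube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
        const int j0 = std::max(0, p - dj), j1 = std::min(W, W + p - dj);
        const float* colbase = colT.colptr(r);
        for (int j = j0; j < j1; ++j) {
          float* dst = &out(i0 + di - p, j + dj - p, c);
          const float* src = colbase + j * H + i0;
          const int n = i1 - i0;
          for (int i = 0; i < n; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& Wm,
                       const arma::vec& b, const int k, const int p) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_rows;
  fmat colT = im2colT_(as_f(x), k, p);
  fmat out = colT * as_f(Wm).t();        // (H*W) x Cout
  frowvec bf = conv_to<frowvec>::from(b.t());
  out.each_row() += bf;
  cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c) {
    const float* src = out.colptr(c);
    double* dst = y.slice_memptr(c);
    for (int i = 0; i < H * W; ++i) dst[i] = src[i];
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::cube& dout,
                       const arma::mat& Wm, const int k, const int p,
                       const bool need_dx) {
  const int H = dout.n_rows, W = dout.n_cols, Cout = dout.n_slices;
  const int Cin = x.n_slices;
  fmat colT = im2colT_(as_f(x), k, p);
  fcube df = as_f(dout);
  fmat dmat(df.memptr(), H * W, Cout, false, true);  // HW x Cout view
  fmat dW = dmat.t() * colT;                         // Cout x (C*k*k)
  fvec db = conv_to<fvec>::from(sum(dmat, 0).t());
  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = conv_to<vec>::from(db));
  if (need_dx) {
    fmat dcolT = dmat * as_f(Wm);                    // HW x (C*k*k)
    res["dx"] = conv_to<cube>::from(col2imT_(dcolT, H, W, Cin, k, p));
  }
  return res;
}
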