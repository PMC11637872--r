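// Minimal convolution kernels for the detector: im2col + GEMM forward,
// exact analytic backward. Arrays are H x W x C cubes (column-major, as
// produced by R's array()); filters are (k*k*Cin) x Cout matrices with
// patch index ki + k*kj + k*k*c (ki fastest).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, const int k, const int stride, const int pad,
                  const int Ho, const int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(Ho * Wo, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword col_idx = (uword)ki + (uword)k * kj + (uword)k * k * c;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            cols((uword)oi + (uword)Ho * oj, col_idx) = x(i, j, c);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k, const int stride, const int pad,
                   const int Ho, const int Wo) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword col_idx = (uword)ki + (uword)k * kj + (uword)k * k * c;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            x(i, j, c) += cols((uword)oi + (uword)Ho * oj, col_idx);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fw_cpp(const arma::cube& x, const arma::mat& Wm,
                         const arma::vec& b, const int k, const int stride,
                         const int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.n_cols;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat y = cols * Wm;
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// Forward that also returns the im2col matrix so the backward pass can
// reuse it instead of rebuilding patches.
// [[Rcpp::export]]
Rcpp::List conv2d_fwc_cpp(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, const int k, const int stride,
                          const int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.n_cols;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat y = cols * Wm;
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("cols") = cols);
}

// Backward from cached im2col columns.
// [[Rcpp::export]]
Rcpp::List conv2d_bwc_cpp(const arma::mat& cols, const arma::mat& Wm,
                          const int k, const int stride, const int pad,
                          const arma::cube& dy, const int H, const int W,
                          const int C) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat dym((double*)dy.memptr(), (uword)Ho * Wo, Cout);
  mat dW = cols.t() * dym;
  vec db = sum(dym, 0).t();
  mat dcols = dym * Wm.t();
  cube dx = col2im(dcols, H, W, C, k, stride, pad, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw_cpp(const arma::cube& x, const arma::mat& Wm, const int k,
                         const int stride, const int pad, const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat dym((double*)dy.memptr(), (uword)Ho * Wo, Cout);
  mat dW = cols.t() * dym;
  vec db = sum(dym, 0).t();
  mat dcols = dym * Wm.t();
  cube dx = col2im(dcols, H, W, C, k, stride, pad, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Max pooling, stride 1 friendly (used by the SPPF block with k=5, pad=2).
// Returns pooled cube plus 1-based argmax linear indices into x.
// [[Rcpp::export]]
Rcpp::List maxpool_fw_cpp(const arma::cube& x, const int k, const int stride,
                          const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -datum::inf;
        uword best_idx = 0;
        for (int kj = 0; kj < k; ++kj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            const double v = x(i, j, c);
            if (v > best) {
              best = v;
              best_idx = (uword)i + (uword)H * j + (uword)H * W * c;
            }
          }
        }
        y(oi, oj, c) = best;
        idx(oi, oj, c) = best_idx + 1;  // 1-based for R
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bw_cpp(const arma::ucube& idx, const arma::cube& dy,
                          const int H, const int W, const int C) {
  cube dx(H, W, C, fill::zeros);
  const uword n = dy.n_elem;
  const double* dyp = dy.memptr();
  const uword* ip = idx.memptr();
  double* dxp = dx.memptr();
  for (uword t = 0; t < n; ++t) dxp[ip[t] - 1] += dyp[t];
  return dx;
}
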