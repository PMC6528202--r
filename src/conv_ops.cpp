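// Convolution primitives for the network engine.
// Layout: images/feature maps are R arrays dim = c(H, W, C) (column-major),
// weights dim = c(k, k, Cin, Cout).  Stride/pad are scalar ints; padding is
// symmetric zero padding.  Backward recomputes the im2col matrix rather than
// caching it: memory stays flat across deep nets at the cost of one gemm-side
// rearrangement, which is cheap at the image sizes this package targets.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col: returns (k*k*Cin) x (Ho*Wo) matrix; column index runs over output
// positions in column-major (row fastest) order to match R array layout.
static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int r0 = ho * stride - pad, c0 = wo * stride - pad;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kc = 0; kc < k; ++kc) {
          const int cc = c0 + kc;
          for (int kr = 0; kr < k; ++kr) {
            const int rr = r0 + kr;
            const int idx = c * k * k + kc * k + kr;
            if (rr >= 0 && rr < H && cc >= 0 && cc < W)
              dst[idx] = x(rr, cc, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im(const arma::mat& cols, arma::cube& x, int k, int stride,
                   int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int r0 = ho * stride - pad, c0 = wo * stride - pad;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kc = 0; kc < k; ++kc) {
          const int cc = c0 + kc;
          for (int kr = 0; kr < k; ++kr) {
            const int rr = r0 + kr;
            if (rr >= 0 && rr < H && cc >= 0 && cc < W)
              x(rr, cc, c) += src[c * k * k + kc * k + kr];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::cube& w_flat,
                     const arma::vec& b, int k, int cout, int stride, int pad) {
  // w_flat arrives as cube (k, k, Cin*Cout); reshape to (k*k*Cin) x Cout
  const int cin = x.n_slices;
  const int Ho = out_dim(x.n_rows, k, stride, pad);
  const int Wo = out_dim(x.n_cols, k, stride, pad);
  arma::mat wm(const_cast<double*>(w_flat.memptr()), k * k * cin, cout, false, true);
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat y = wm.t() * cols;          // Cout x (Ho*Wo)
  y.each_col() += b;
  arma::cube out(Ho, Wo, cout);
  for (int c = 0; c < cout; ++c)
    for (int j = 0; j < Ho * Wo; ++j)
      out.slice(c)(j % Ho, j / Ho) = y(c, j);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const arma::cube& x, const arma::cube& w_flat,
               const arma::cube& dy, int k, int stride, int pad) {
  const int cin = x.n_slices, cout = dy.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  arma::mat wm(const_cast<double*>(w_flat.memptr()), k * k * cin, cout, false, true);
  arma::mat dym(cout, Ho * Wo);
  for (int c = 0; c < cout; ++c)
    for (int j = 0; j < Ho * Wo; ++j)
      dym(c, j) = dy.slice(c)(j % Ho, j / Ho);

  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat dwm = cols * dym.t();               // (k*k*Cin) x Cout
  arma::vec db = arma::sum(dym, 1);
  arma::mat dcols = wm * dym;                   // (k*k*Cin) x (Ho*Wo)
  arma::cube dx(x.n_rows, x.n_cols, cin, arma::fill::zeros);
  col2im(dcols, dx, k, stride, pad, Ho, Wo);

  arma::cube dw(k, k, cin * cout);
  std::memcpy(dw.memptr(), dwm.memptr(), sizeof(double) * dwm.n_elem);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export(name = ".upsample2_fw")]]
arma::cube upsample2_fw(const arma::cube& x) {
  arma::cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (unsigned c = 0; c < x.n_slices; ++c)
    for (unsigned j = 0; j < x.n_cols; ++j)
      for (unsigned i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::cube upsample2_bw(const arma::cube& dy) {
  arma::cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (unsigned c = 0; c < dy.n_slices; ++c)
    for (unsigned j = 0; j < dx.n_cols; ++j)
      for (unsigned i = 0; i < dx.n_rows; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
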