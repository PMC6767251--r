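// Minimal convolution kernels for the sinogram-inpainting networks.
//
// Tensors are R arrays with dim (C, H, W, B), column-major, so each sample is
// a C x (H*W) matrix. Convolutions are realised as im2col + GEMM in single
// precision (the networks are trained in float; gradients are returned as
// doubles to R). The im2col buffers are concatenated across the batch so
// every layer costs a single GEMM per direction. Weight matrices are
// (C_out x C_in*k*k) for plain convolutions and (C_in x C_out*k*k) for
// transposed convolutions; the row ordering inside the k*k block is internal
// and consistent between the gather (im2col) and scatter (col2im) paths.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather one sample's patches into columns [col0, col0 + Ho*Wo) of K.
static void im2col(const float* x, int C, int H, int W, int k, int stride,
                   int pad, int Ho, int Wo, fmat& K, size_t col0) {
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      float* Kc = K.colptr(col0 + (size_t)ho + (size_t)Ho * wo);
      for (int kh = 0; kh < k; ++kh) {
        const int hh = h0 + kh;
        if (hh < 0 || hh >= H) continue;
        for (int kw = 0; kw < k; ++kw) {
          const int ww = w0 + kw;
          if (ww < 0 || ww >= W) continue;
          const float* xp = x + (size_t)C * (hh + (size_t)H * ww);
          std::copy(xp, xp + C, Kc + (size_t)C * (kh * k + kw));
        }
      }
    }
  }
}

// Scatter-add columns [col0, col0 + Ho*Wo) of G into one sample's grid.
static void col2im(const fmat& G, int C, int H, int W, int k, int stride,
                   int pad, int Ho, int Wo, float* dx, size_t col0) {
  std::fill(dx, dx + (size_t)C * H * W, 0.0f);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      const float* Gc = G.colptr(col0 + (size_t)ho + (size_t)Ho * wo);
      for (int kh = 0; kh < k; ++kh) {
        const int hh = h0 + kh;
        if (hh < 0 || hh >= H) continue;
        for (int kw = 0; kw < k; ++kw) {
          const int ww = w0 + kw;
          if (ww < 0 || ww >= W) continue;
          const float* gp = Gc + (size_t)C * (kh * k + kw);
          float* xp = dx + (size_t)C * (hh + (size_t)H * ww);
          for (int c = 0; c < C; ++c) xp[c] += gp[c];
        }
      }
    }
  }
}

static fmat to_f(const NumericMatrix& m) {
  fmat f(m.nrow(), m.ncol());
  const double* p = REAL(m);
  for (size_t i = 0; i < f.n_elem; ++i) f[i] = (float)p[i];
  return f;
}

static fmat to_fmat(const double* x, size_t nr, size_t nc) {
  fmat f(nr, nc);
  const size_t n = nr * nc;
  for (size_t i = 0; i < n; ++i) f[i] = (float)x[i];
  return f;
}

static void write_double(const fmat& f, double* out) {
  for (size_t i = 0; i < f.n_elem; ++i) out[i] = (double)f[i];
}

// Build the batch-concatenated im2col matrix of x: (C*k*k) x (Ho*Wo*B).
static fmat im2col_batch(const double* x, int C, int H, int W, int B,
                         int k, int stride, int pad, int Ho, int Wo) {
  fmat K((size_t)C * k * k, (size_t)Ho * Wo * B, arma::fill::zeros);
  std::vector<float> xf((size_t)C * H * W);
  const size_t xs = (size_t)C * H * W;
  for (int s = 0; s < B; ++s) {
    const double* xp = x + (size_t)s * xs;
    for (size_t i = 0; i < xs; ++i) xf[i] = (float)xp[i];
    im2col(xf.data(), C, H, W, k, stride, pad, Ho, Wo, K,
           (size_t)s * Ho * Wo);
  }
  return K;
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(const NumericVector& x, const IntegerVector& xdim,
                          const NumericMatrix& W, const NumericVector& bias,
                          int k, int stride, int pad) {
  const int C = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  const int Co = W.nrow();
  const int Ho = conv_out(H, k, stride, pad), Wo = conv_out(Wd, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  if (W.ncol() != C * k * k) stop("weight shape mismatch");
  fmat Wf = to_f(W);
  fmat K = im2col_batch(REAL(x), C, H, Wd, B, k, stride, pad, Ho, Wo);
  fmat Y = Wf * K;  // Co x (Ho*Wo*B)
  NumericVector y((R_xlen_t)Co * Ho * Wo * B);
  double* yp = REAL(y);
  for (size_t j = 0; j < Y.n_cols; ++j) {
    const float* Yc = Y.colptr(j);
    double* yj = yp + (size_t)Co * j;
    for (int co = 0; co < Co; ++co) yj[co] = (double)Yc[co] + bias[co];
  }
  y.attr("dim") = IntegerVector::create(Co, Ho, Wo, B);
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(const NumericVector& x, const IntegerVector& xdim,
                 const NumericMatrix& W, const NumericVector& dy,
                 int k, int stride, int pad, bool want_dx,
                 bool want_dw = true) {
  const int C = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  const int Co = W.nrow();
  const int Ho = conv_out(H, k, stride, pad), Wo = conv_out(Wd, k, stride, pad);
  fmat dY = to_fmat(REAL(dy), Co, (size_t)Ho * Wo * B);
  List out = List::create(_["dW"] = R_NilValue, _["db"] = R_NilValue,
                          _["dx"] = R_NilValue);
  if (want_dw) {
    fmat K = im2col_batch(REAL(x), C, H, Wd, B, k, stride, pad, Ho, Wo);
    fmat dW = dY * K.t();
    arma::fvec db = arma::sum(dY, 1);
    NumericMatrix dWr(Co, C * k * k);
    write_double(dW, REAL(dWr));
    NumericVector dbr(Co);
    for (int i = 0; i < Co; ++i) dbr[i] = (double)db[i];
    out["dW"] = dWr; out["db"] = dbr;
  }
  if (want_dx) {
    fmat Wf = to_f(W);
    fmat G = Wf.t() * dY;  // (C*k*k) x (Ho*Wo*B)
    NumericVector dx((R_xlen_t)C * H * Wd * B);
    std::vector<float> dxbuf((size_t)C * H * Wd);
    const size_t xs = (size_t)C * H * Wd;
    for (int s = 0; s < B; ++s) {
      col2im(G, C, H, Wd, k, stride, pad, Ho, Wo, dxbuf.data(),
             (size_t)s * Ho * Wo);
      double* dxp = REAL(dx) + (size_t)s * xs;
      for (size_t i = 0; i < xs; ++i) dxp[i] = (double)dxbuf[i];
    }
    dx.attr("dim") = IntegerVector::create(C, H, Wd, B);
    out["dx"] = dx;
  }
  return out;
}

// Transposed convolution: output (Co, H*stride, W*stride, B) such that a
// plain convolution with the same (k, stride, pad) maps the output size back
// to the input size. Weights are (Ci x Co*k*k).
// [[Rcpp::export]]
NumericVector nn_convt_fwd(const NumericVector& x, const IntegerVector& xdim,
                           const NumericMatrix& W, const NumericVector& bias,
                           int k, int stride, int pad) {
  const int Ci = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  if (W.nrow() != Ci) stop("weight shape mismatch");
  const int Co = W.ncol() / (k * k);
  const int Ho = stride * (H - 1) - 2 * pad + k;
  const int Wo = stride * (Wd - 1) - 2 * pad + k;
  fmat Wf = to_f(W);
  fmat X = to_fmat(REAL(x), Ci, (size_t)H * Wd * B);
  fmat G = Wf.t() * X;  // (Co*k*k) x (H*W*B)
  NumericVector y((R_xlen_t)Co * Ho * Wo * B);
  std::vector<float> ybuf((size_t)Co * Ho * Wo);
  const size_t ys = (size_t)Co * Ho * Wo;
  for (int s = 0; s < B; ++s) {
    col2im(G, Co, Ho, Wo, k, stride, pad, H, Wd, ybuf.data(),
           (size_t)s * H * Wd);
    double* yp = REAL(y) + (size_t)s * ys;
    for (int j = 0; j < Ho * Wo; ++j)
      for (int co = 0; co < Co; ++co)
        yp[co + (size_t)Co * j] = (double)ybuf[co + (size_t)Co * j] + bias[co];
  }
  y.attr("dim") = IntegerVector::create(Co, Ho, Wo, B);
  return y;
}

// [[Rcpp::export]]
List nn_convt_bwd(const NumericVector& x, const IntegerVector& xdim,
                  const NumericMatrix& W, const NumericVector& dy,
                  int k, int stride, int pad, bool want_dx) {
  const int Ci = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  const int Co = W.ncol() / (k * k);
  const int Ho = stride * (H - 1) - 2 * pad + k;
  const int Wo = stride * (Wd - 1) - 2 * pad + k;
  fmat K = im2col_batch(REAL(dy), Co, Ho, Wo, B, k, stride, pad, H, Wd);
  fmat X = to_fmat(REAL(x), Ci, (size_t)H * Wd * B);
  fmat dW = X * K.t();  // Ci x (Co*k*k)
  fmat dY = to_fmat(REAL(dy), Co, (size_t)Ho * Wo * B);
  arma::fvec db = arma::sum(dY, 1);
  NumericMatrix dWr(Ci, Co * k * k);
  write_double(dW, REAL(dWr));
  NumericVector dbr(Co);
  for (int i = 0; i < Co; ++i) dbr[i] = (double)db[i];
  List out = List::create(_["dW"] = dWr, _["db"] = dbr,
                          _["dx"] = R_NilValue);
  if (want_dx) {
    fmat Wf = to_f(W);
    fmat dX = Wf * K;  // Ci x (H*W*B)
    NumericVector dx((R_xlen_t)Ci * H * Wd * B);
    write_double(dX, REAL(dx));
    dx.attr("dim") = IntegerVector::create(Ci, H, Wd, B);
    out["dx"] = dx;
  }
  return out;
}
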