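// Float-resident parameter store for training. Weights, Adam moments and
// gradient accumulators live as single-precision Armadillo matrices behind an
// external pointer, so an optimisation step never round-trips multi-million-
// element arrays through R. Layer kernels mirror the ones in nn_ops.cpp but
// read weights from / accumulate gradients into the store.

#include <RcppArmadillo.h>
#include <map>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;

struct ParamStore {
  std::map<std::string, fmat> p, m, v, g;
  std::map<std::string, bool> is_vec;
};

typedef XPtr<ParamStore> StorePtr;

// helpers shared with nn_ops.cpp (duplicated statics; file-local linkage)
static inline int conv_out2(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col2(const float* x, int C, int H, int W, int k, int stride,
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

static void col2im2(const fmat& G, int C, int H, int W, int k, int stride,
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

static fmat im2col_batch2(const double* x, int C, int H, int W, int B,
                          int k, int stride, int pad, int Ho, int Wo) {
  fmat K((size_t)C * k * k, (size_t)Ho * Wo * B, arma::fill::zeros);
  std::vector<float> xf((size_t)C * H * W);
  const size_t xs = (size_t)C * H * W;
  for (int s = 0; s < B; ++s) {
    const double* xp = x + (size_t)s * xs;
    for (size_t i = 0; i < xs; ++i) xf[i] = (float)xp[i];
    im2col2(xf.data(), C, H, W, k, stride, pad, Ho, Wo, K,
            (size_t)s * Ho * Wo);
  }
  return K;
}

static fmat to_fmat2(const double* x, size_t nr, size_t nc) {
  fmat f(nr, nc);
  const size_t n = nr * nc;
  for (size_t i = 0; i < n; ++i) f[i] = (float)x[i];
  return f;
}

// [[Rcpp::export]]
SEXP cpp_store_create() {
  return StorePtr(new ParamStore(), true);
}

// [[Rcpp::export]]
void cpp_store_set(SEXP sp, std::string name, const NumericVector& value,
                   int n_rows, int n_cols, bool is_vec) {
  StorePtr store(sp);
  fmat f(n_rows, n_cols);
  for (size_t i = 0; i < f.n_elem; ++i) f[i] = (float)value[i];
  store->p[name] = f;
  store->m[name] = fmat(n_rows, n_cols, arma::fill::zeros);
  store->v[name] = fmat(n_rows, n_cols, arma::fill::zeros);
  store->g[name] = fmat(n_rows, n_cols, arma::fill::zeros);
  store->is_vec[name] = is_vec;
}

// [[Rcpp::export]]
SEXP cpp_store_get(SEXP sp, std::string name) {
  StorePtr store(sp);
  const fmat& f = store->p.at(name);
  if (store->is_vec.at(name)) {
    NumericVector out(f.n_elem);
    for (size_t i = 0; i < f.n_elem; ++i) out[i] = (double)f[i];
    return out;
  }
  NumericMatrix out(f.n_rows, f.n_cols);
  for (size_t i = 0; i < f.n_elem; ++i) REAL(out)[i] = (double)f[i];
  return out;
}

// [[Rcpp::export]]
void cpp_store_add_grad(SEXP sp, std::string name,
                        const NumericVector& grad) {
  StorePtr store(sp);
  fmat& g = store->g.at(name);
  for (size_t i = 0; i < g.n_elem; ++i) g[i] += (float)grad[i];
}

// [[Rcpp::export]]
void cpp_store_zero_grads(SEXP sp) {
  StorePtr store(sp);
  for (auto& kv : store->g) kv.second.zeros();
}

// [[Rcpp::export]]
void cpp_store_adam(SEXP sp, double lr, double beta1, double beta2,
                    double bc1, double bc2, double eps) {
  StorePtr store(sp);
  const float b1 = (float)beta1, b2 = (float)beta2;
  const float flr = (float)lr, fbc1 = (float)bc1, fbc2 = (float)bc2;
  const float fe = (float)eps;
  const float ibc1 = 1.0f / fbc1, ibc2 = 1.0f / fbc2;
  for (auto& kv : store->p) {
    const std::string& nm = kv.first;
    float* __restrict p = kv.second.memptr();
    float* __restrict m = store->m.at(nm).memptr();
    float* __restrict v = store->v.at(nm).memptr();
    const float* __restrict g = store->g.at(nm).memptr();
    const size_t n = kv.second.n_elem;
    for (size_t i = 0; i < n; ++i) {
      m[i] = b1 * m[i] + (1.0f - b1) * g[i];
      v[i] = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
      p[i] -= flr * (m[i] * ibc1) / (std::sqrt(v[i] * ibc2) + fe);
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd_s(const NumericVector& x, const IntegerVector& xdim,
                            SEXP sp, std::string wname, std::string bname,
                            int k, int stride, int pad) {
  StorePtr store(sp);
  const fmat& Wf = store->p.at(wname);
  const fmat& bias = store->p.at(bname);
  const int C = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  const int Co = Wf.n_rows;
  const int Ho = conv_out2(H, k, stride, pad);
  const int Wo = conv_out2(Wd, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  fmat K = im2col_batch2(REAL(x), C, H, Wd, B, k, stride, pad, Ho, Wo);
  fmat Y = Wf * K;
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
SEXP nn_conv_bwd_s(const NumericVector& x, const IntegerVector& xdim,
                   SEXP sp, std::string wname, std::string bname,
                   const NumericVector& dy, int k, int stride, int pad,
                   bool want_dx, bool want_dw) {
  StorePtr store(sp);
  const fmat& Wf = store->p.at(wname);
  const int C = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  const int Co = Wf.n_rows;
  const int Ho = conv_out2(H, k, stride, pad);
  const int Wo = conv_out2(Wd, k, stride, pad);
  fmat dY = to_fmat2(REAL(dy), Co, (size_t)Ho * Wo * B);
  if (want_dw) {
    fmat K = im2col_batch2(REAL(x), C, H, Wd, B, k, stride, pad, Ho, Wo);
    store->g.at(wname) += dY * K.t();
    store->g.at(bname) += arma::sum(dY, 1);
  }
  if (!want_dx) return R_NilValue;
  fmat G = Wf.t() * dY;
  NumericVector dx((R_xlen_t)C * H * Wd * B);
  std::vector<float> dxbuf((size_t)C * H * Wd);
  const size_t xs = (size_t)C * H * Wd;
  for (int s = 0; s < B; ++s) {
    col2im2(G, C, H, Wd, k, stride, pad, Ho, Wo, dxbuf.data(),
            (size_t)s * Ho * Wo);
    double* dxp = REAL(dx) + (size_t)s * xs;
    for (size_t i = 0; i < xs; ++i) dxp[i] = (double)dxbuf[i];
  }
  dx.attr("dim") = IntegerVector::create(C, H, Wd, B);
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_convt_fwd_s(const NumericVector& x,
                             const IntegerVector& xdim, SEXP sp,
                             std::string wname, std::string bname,
                             int k, int stride, int pad) {
  StorePtr store(sp);
  const fmat& Wf = store->p.at(wname);
  const fmat& bias = store->p.at(bname);
  const int Ci = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  const int Co = Wf.n_cols / (k * k);
  const int Ho = stride * (H - 1) - 2 * pad + k;
  const int Wo = stride * (Wd - 1) - 2 * pad + k;
  fmat X = to_fmat2(REAL(x), Ci, (size_t)H * Wd * B);
  fmat G = Wf.t() * X;
  NumericVector y((R_xlen_t)Co * Ho * Wo * B);
  std::vector<float> ybuf((size_t)Co * Ho * Wo);
  const size_t ys = (size_t)Co * Ho * Wo;
  for (int s = 0; s < B; ++s) {
    col2im2(G, Co, Ho, Wo, k, stride, pad, H, Wd, ybuf.data(),
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
SEXP nn_convt_bwd_s(const NumericVector& x, const IntegerVector& xdim,
                    SEXP sp, std::string wname, std::string bname,
                    const NumericVector& dy, int k, int stride, int pad,
                    bool want_dx) {
  StorePtr store(sp);
  const fmat& Wf = store->p.at(wname);
  const int Ci = xdim[0], H = xdim[1], Wd = xdim[2], B = xdim[3];
  const int Co = Wf.n_cols / (k * k);
  const int Ho = stride * (H - 1) - 2 * pad + k;
  const int Wo = stride * (Wd - 1) - 2 * pad + k;
  fmat K = im2col_batch2(REAL(dy), Co, Ho, Wo, B, k, stride, pad, H, Wd);
  fmat X = to_fmat2(REAL(x), Ci, (size_t)H * Wd * B);
  store->g.at(wname) += X * K.t();
  fmat dY = to_fmat2(REAL(dy), Co, (size_t)Ho * Wo * B);
  store->g.at(bname) += arma::sum(dY, 1);
  if (!want_dx) return R_NilValue;
  fmat dX = Wf * K;
  NumericVector dx((R_xlen_t)Ci * H * Wd * B);
  for (size_t i = 0; i < dX.n_elem; ++i) REAL(dx)[i] = (double)dX[i];
  dx.attr("dim") = IntegerVector::create(Ci, H, Wd, B);
  return dx;
}
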