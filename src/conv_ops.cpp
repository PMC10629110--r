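// Compiled convolution kernels.
//
// Tensor layout matches the R side: column-major arrays (N, H, W, C) with
// the batch index fastest. Dense convolutions run as im2col gathers plus a
// BLAS matrix product (via Armadillo); depth-wise convolutions and the
// stride-2 transposed convolution use direct loops. Convolution arithmetic
// is single precision internally (inputs/outputs stay double on the R
// side): on the memory-bandwidth-bound loops this halves traffic, and the
// float rounding noise is far below the stochastic-gradient noise floor.
// The im2col matrix built in the forward pass is handed back to R as an
// external pointer and reused by the backward pass instead of being rebuilt.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::fmat fmat;

static inline fmat im2col_f(const double* x, int N, int H, int W, int C,
                            int kh, int kw, int stride, int ph, int pw,
                            int Ho, int Wo) {
  const int L = Ho * Wo, K = kh * kw;
  fmat X(static_cast<arma::uword>(N) * L, static_cast<arma::uword>(K) * C,
         arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const arma::uword col = a + kh * b + static_cast<arma::uword>(K) * c;
        float* dst = X.colptr(col);
        int oh_lo = 0, oh_hi = Ho - 1;
        while (oh_lo <= oh_hi && oh_lo * stride + a - ph < 0) ++oh_lo;
        while (oh_hi >= oh_lo && oh_hi * stride + a - ph >= H) --oh_hi;
        if (oh_lo > oh_hi) continue;
        const int span = oh_hi - oh_lo + 1;
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * stride + b - pw;
          if (wi < 0 || wi >= W) continue;
          const double* src = x + static_cast<size_t>(N) *
              ((oh_lo * stride + a - ph) +
               static_cast<size_t>(H) * (wi + static_cast<size_t>(W) * c));
          float* d0 = dst + static_cast<size_t>(N) * (oh_lo + static_cast<size_t>(Ho) * ow);
          if (stride == 1) {
            const size_t m = static_cast<size_t>(N) * span;
            for (size_t j = 0; j < m; ++j) d0[j] = static_cast<float>(src[j]);
          } else {
            for (int j = 0; j < span; ++j) {
              const double* s0 = src + static_cast<size_t>(N) * j * stride;
              float* dd = d0 + static_cast<size_t>(N) * j;
              for (int n = 0; n < N; ++n) dd[n] = static_cast<float>(s0[n]);
            }
          }
        }
      }
    }
  }
  return X;
}

static inline fmat to_fmat(const double* p, arma::uword nr, arma::uword nc) {
  fmat out(nr, nc);
  const arma::uword m = nr * nc;
  float* o = out.memptr();
  for (arma::uword i = 0; i < m; ++i) o[i] = static_cast<float>(p[i]);
  return out;
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp", rng = false)]]
List conv2d_fwd_cpp(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector bias, int stride, int ph, int pw) {
  const int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * ph - kh) / stride + 1;
  const int Wo = (W + 2 * pw - kw) / stride + 1;
  const int L = Ho * Wo, K = kh * kw;
  fmat* Xp = new fmat(im2col_f(x.begin(), N, H, W, C, kh, kw, stride, ph, pw,
                               Ho, Wo));
  fmat Wm = to_fmat(w.begin(), static_cast<arma::uword>(K) * C, Cout);
  fmat Y = (*Xp) * Wm;
  if (bias.size() == static_cast<size_t>(Cout)) {
    for (int co = 0; co < Cout; ++co) Y.col(co) += static_cast<float>(bias[co]);
  }
  NumericVector out(static_cast<R_xlen_t>(N) * L * Cout);
  double* op = out.begin();
  const float* yp = Y.memptr();
  const size_t m = static_cast<size_t>(N) * L * Cout;
  for (size_t i = 0; i < m; ++i) op[i] = static_cast<double>(yp[i]);
  out.attr("dim") = IntegerVector::create(N, Ho, Wo, Cout);
  XPtr<fmat> px(Xp, true);
  return List::create(Named("out") = out, Named("xcol") = px);
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp", rng = false)]]
List conv2d_bwd_cpp(NumericVector dy, SEXP xcol, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    int stride, int ph, int pw, bool has_bias) {
  const int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * ph - kh) / stride + 1;
  const int Wo = (W + 2 * pw - kw) / stride + 1;
  const int L = Ho * Wo, K = kh * kw;
  XPtr<fmat> Xp(xcol);
  fmat dY = to_fmat(dy.begin(), static_cast<arma::uword>(N) * L, Cout);
  fmat Wm = to_fmat(w.begin(), static_cast<arma::uword>(K) * C, Cout);
  fmat dWm = Xp->t() * dY;
  fmat dXcol = dY * Wm.t();

  NumericVector dx(static_cast<R_xlen_t>(N) * H * W * C);
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const arma::uword col = a + kh * b + static_cast<arma::uword>(K) * c;
        const float* src = dXcol.colptr(col);
        int oh_lo = 0, oh_hi = Ho - 1;
        while (oh_lo <= oh_hi && oh_lo * stride + a - ph < 0) ++oh_lo;
        while (oh_hi >= oh_lo && oh_hi * stride + a - ph >= H) --oh_hi;
        if (oh_lo > oh_hi) continue;
        const int span = oh_hi - oh_lo + 1;
        for (int ow = 0; ow < Wo; ++ow) {
          const int wi = ow * stride + b - pw;
          if (wi < 0 || wi >= W) continue;
          double* dst = dxp + static_cast<size_t>(N) *
              ((oh_lo * stride + a - ph) +
               static_cast<size_t>(H) * (wi + static_cast<size_t>(W) * c));
          const float* s = src + static_cast<size_t>(N) * (oh_lo + static_cast<size_t>(Ho) * ow);
          if (stride == 1) {
            const size_t m = static_cast<size_t>(N) * span;
            for (size_t j = 0; j < m; ++j) dst[j] += s[j];
          } else {
            for (int j = 0; j < span; ++j) {
              double* d0 = dst + static_cast<size_t>(N) * j * stride;
              const float* s0 = s + static_cast<size_t>(N) * j;
              for (int n = 0; n < N; ++n) d0[n] += s0[n];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(N, H, W, C);

  NumericVector dwv(static_cast<R_xlen_t>(K) * C * Cout);
  {
    double* dp = dwv.begin();
    const float* sp = dWm.memptr();
    const size_t m = static_cast<size_t>(K) * C * Cout;
    for (size_t i = 0; i < m; ++i) dp[i] = static_cast<double>(sp[i]);
  }
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);

  if (has_bias) {
    arma::frowvec dbv = arma::sum(dY, 0);
    NumericVector db(Cout);
    for (int co = 0; co < Cout; ++co) db[co] = static_cast<double>(dbv[co]);
    return List::create(Named("dx") = dx, Named("dw") = dwv, Named("db") = db);
  }
  return List::create(Named("dx") = dx, Named("dw") = dwv,
                      Named("db") = R_NilValue);
}

// [[Rcpp::export(name = ".dwconv_fwd_cpp", rng = false)]]
List dwconv_fwd_cpp(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector bias) {
  const int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t total = static_cast<size_t>(N) * H * W * C;
  arma::fvec* fx = new arma::fvec(total);
  {
    float* fp = fx->memptr();
    const double* dp = x.begin();
    for (size_t i = 0; i < total; ++i) fp[i] = static_cast<float>(dp[i]);
  }
  std::vector<float> fy(total, 0.0f);
  const float* xp = fx->memptr();
  float* yp = fy.data();
  const bool hb = bias.size() == static_cast<size_t>(C);
  for (int c = 0; c < C; ++c) {
    const size_t coff = static_cast<size_t>(N) * H * W * c;
    if (hb) std::fill(yp + coff, yp + coff + static_cast<size_t>(N) * H * W,
                      static_cast<float>(bias[c]));
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const float wv = static_cast<float>(w[a + kh * b + kh * kw * c]);
        if (wv == 0.0f) continue;
        const int ho_lo = std::max(0, ph - a);
        const int ho_hi = std::min(H - 1, H - 1 + ph - a);
        if (ho_lo > ho_hi) continue;
        const size_t m = static_cast<size_t>(N) * (ho_hi - ho_lo + 1);
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + b - pw;
          if (wi < 0 || wi >= W) continue;
          float* dst = yp + coff + static_cast<size_t>(N) * (ho_lo + static_cast<size_t>(H) * wo);
          const float* src = xp + coff + static_cast<size_t>(N) * ((ho_lo + a - ph) + static_cast<size_t>(H) * wi);
          for (size_t j = 0; j < m; ++j) dst[j] += wv * src[j];
        }
      }
    }
  }
  NumericVector y(total);
  {
    double* dp = y.begin();
    for (size_t i = 0; i < total; ++i) dp[i] = static_cast<double>(yp[i]);
  }
  y.attr("dim") = IntegerVector::create(N, H, W, C);
  XPtr<arma::fvec> px(fx, true);
  return List::create(Named("out") = y, Named("fx") = px);
}

// [[Rcpp::export(name = ".dwconv_bwd_cpp", rng = false)]]
List dwconv_bwd_cpp(NumericVector dy, SEXP fxp, IntegerVector xd,
                    NumericVector w, IntegerVector wd, bool has_bias) {
  const int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t total = static_cast<size_t>(N) * H * W * C;
  XPtr<arma::fvec> fx(fxp);
  const float* xp = fx->memptr();
  std::vector<float> fdy(total);
  {
    const double* dp = dy.begin();
    for (size_t i = 0; i < total; ++i) fdy[i] = static_cast<float>(dp[i]);
  }
  std::vector<float> fdx(total, 0.0f);
  NumericVector dwv(static_cast<R_xlen_t>(kh) * kw * C);
  NumericVector db(has_bias ? C : 0);
  const float* dyp = fdy.data();
  float* dxp = fdx.data();
  for (int c = 0; c < C; ++c) {
    const size_t coff = static_cast<size_t>(N) * H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const float wv = static_cast<float>(w[a + kh * b + kh * kw * c]);
        double acc = 0.0;
        const int ho_lo = std::max(0, ph - a);
        const int ho_hi = std::min(H - 1, H - 1 + ph - a);
        if (ho_lo > ho_hi) continue;
        const size_t m = static_cast<size_t>(N) * (ho_hi - ho_lo + 1);
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + b - pw;
          if (wi < 0 || wi >= W) continue;
          const float* dyo = dyp + coff + static_cast<size_t>(N) * (ho_lo + static_cast<size_t>(H) * wo);
          const float* xi = xp + coff + static_cast<size_t>(N) * ((ho_lo + a - ph) + static_cast<size_t>(H) * wi);
          float* dxi = dxp + coff + static_cast<size_t>(N) * ((ho_lo + a - ph) + static_cast<size_t>(H) * wi);
          float facc = 0.0f;
          for (size_t j = 0; j < m; ++j) {
            facc += dyo[j] * xi[j];
            dxi[j] += wv * dyo[j];
          }
          acc += static_cast<double>(facc);
        }
        dwv[a + kh * b + kh * kw * c] = acc;
      }
    }
    if (has_bias) {
      double s = 0.0;
      for (size_t i = 0; i < static_cast<size_t>(N) * H * W; ++i)
        s += static_cast<double>(dyp[coff + i]);
      db[c] = s;
    }
  }
  NumericVector dx(total);
  {
    double* dp = dx.begin();
    for (size_t i = 0; i < total; ++i) dp[i] = static_cast<double>(dxp[i]);
  }
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C);
  if (has_bias)
    return List::create(Named("dx") = dx, Named("dw") = dwv, Named("db") = db);
  return List::create(Named("dx") = dx, Named("dw") = dwv,
                      Named("db") = R_NilValue);
}

// [[Rcpp::export(name = ".tconv2_fwd_cpp", rng = false)]]
NumericVector tconv2_fwd_cpp(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias) {
  const int N = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int Cout = wd[3];
  const arma::mat X(const_cast<double*>(x.begin()),
                    static_cast<arma::uword>(N) * H * W, Cin, false, true);
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a)
        for (int ci = 0; ci < Cin; ++ci)
          Wm(ci, a + 2 * b + 4 * co) = w[a + 2 * (b + 2 * (ci + static_cast<size_t>(Cin) * co))];
  arma::mat Y = X * Wm;  // (N*H*W, 4*Cout)
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector out(static_cast<R_xlen_t>(N) * H2 * W2 * Cout);
  double* op = out.begin();
  const bool hb = bias.size() == static_cast<size_t>(Cout);
  for (int co = 0; co < Cout; ++co) {
    const size_t coff = static_cast<size_t>(N) * H2 * W2 * co;
    if (hb) std::fill(op + coff, op + coff + static_cast<size_t>(N) * H2 * W2, bias[co]);
    for (int b = 0; b < 2; ++b) {
      for (int a = 0; a < 2; ++a) {
        const double* src = Y.colptr(a + 2 * b + 4 * co);
        for (int wi = 0; wi < W; ++wi) {
          for (int hi = 0; hi < H; ++hi) {
            const double* s = src + static_cast<size_t>(N) * (hi + static_cast<size_t>(H) * wi);
            double* dst = op + coff + static_cast<size_t>(N) *
                          ((2 * hi + a) + static_cast<size_t>(H2) * (2 * wi + b));
            for (int n = 0; n < N; ++n) dst[n] += s[n];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, H2, W2, Cout);
  return out;
}

// [[Rcpp::export(name = ".tconv2_bwd_cpp", rng = false)]]
List tconv2_bwd_cpp(NumericVector dy, NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd, bool has_bias) {
  const int N = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  arma::mat dYk(static_cast<arma::uword>(N) * H * W, 4 * Cout);
  const double* dyp = dy.begin();
  for (int co = 0; co < Cout; ++co) {
    const size_t coff = static_cast<size_t>(N) * H2 * W2 * co;
    for (int b = 0; b < 2; ++b) {
      for (int a = 0; a < 2; ++a) {
        double* dst0 = dYk.colptr(a + 2 * b + 4 * co);
        for (int wi = 0; wi < W; ++wi) {
          for (int hi = 0; hi < H; ++hi) {
            const double* src = dyp + coff + static_cast<size_t>(N) *
                                ((2 * hi + a) + static_cast<size_t>(H2) * (2 * wi + b));
            double* dst = dst0 + static_cast<size_t>(N) * (hi + static_cast<size_t>(H) * wi);
            std::copy(src, src + N, dst);
          }
        }
      }
    }
  }
  const arma::mat X(const_cast<double*>(x.begin()),
                    static_cast<arma::uword>(N) * H * W, Cin, false, true);
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a)
        for (int ci = 0; ci < Cin; ++ci)
          Wm(ci, a + 2 * b + 4 * co) = w[a + 2 * (b + 2 * (ci + static_cast<size_t>(Cin) * co))];
  arma::mat dWm = X.t() * dYk;
  arma::mat dX = dYk * Wm.t();
  NumericVector dx(x.size());
  std::copy(dX.begin(), dX.end(), dx.begin());
  dx.attr("dim") = IntegerVector::create(N, H, W, Cin);
  NumericVector dw(w.size());
  for (int co = 0; co < Cout; ++co)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a)
        for (int ci = 0; ci < Cin; ++ci)
          dw[a + 2 * (b + 2 * (ci + static_cast<size_t>(Cin) * co))] =
            dWm(ci, a + 2 * b + 4 * co);
  dw.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  if (has_bias) {
    NumericVector db(Cout);
    for (int co = 0; co < Cout; ++co) {
      const size_t coff = static_cast<size_t>(N) * H2 * W2 * co;
      double s = 0.0;
      for (size_t i = 0; i < static_cast<size_t>(N) * H2 * W2; ++i) s += dyp[coff + i];
      db[co] = s;
    }
    return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
  }
  return List::create(Named("dx") = dx, Named("dw") = dw,
                      Named("db") = R_NilValue);
}

// Fused batch-norm + ReLU. Normalized activations are cached as floats via
// an external pointer for the backward pass.
// [[Rcpp::export(name = ".bnrelu_fwd_cpp", rng = false)]]
List bnrelu_fwd_cpp(NumericVector x, IntegerVector xd,
                    NumericVector gamma, NumericVector beta,
                    NumericVector rm, NumericVector rv,
                    bool training, double momentum, double eps) {
  const int C = xd[3];
  const size_t NHW = static_cast<size_t>(xd[0]) * xd[1] * xd[2];
  NumericVector out(x.size());
  NumericVector rm_new(C), rv_new(C), invstd(C);
  arma::fvec* xh = new arma::fvec(x.size());
  float* xhp = xh->memptr();
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + NHW * c;
    double mu, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < NHW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu = s / NHW;
      var = std::max(0.0, s2 / NHW - mu * mu);
      rm_new[c] = (1 - momentum) * rm[c] + momentum * mu;
      rv_new[c] = (1 - momentum) * rv[c] + momentum * var;
    } else {
      mu = rm[c]; var = rv[c];
      rm_new[c] = rm[c]; rv_new[c] = rv[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* oc = op + NHW * c;
    float* hc = xhp + NHW * c;
    for (size_t i = 0; i < NHW; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = static_cast<float>(h);
      const double y = h * g + b;
      oc[i] = y > 0.0 ? y : 0.0;
    }
  }
  out.attr("dim") = xd;
  XPtr<arma::fvec> px(xh, true);
  return List::create(Named("out") = out, Named("xhat") = px,
                      Named("invstd") = invstd,
                      Named("rm") = rm_new, Named("rv") = rv_new);
}

// [[Rcpp::export(name = ".bnrelu_bwd_cpp", rng = false)]]
List bnrelu_bwd_cpp(NumericVector dy, NumericVector out, SEXP xhat,
                    IntegerVector xd, NumericVector gamma,
                    NumericVector invstd, bool training) {
  const int C = xd[3];
  const size_t NHW = static_cast<size_t>(xd[0]) * xd[1] * xd[2];
  XPtr<arma::fvec> xh(xhat);
  const float* xhp = xh->memptr();
  const double* dyp = dy.begin();
  const double* op = out.begin();
  NumericVector dx(dy.size());
  NumericVector dgamma(C), dbeta(C);
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* dyc = dyp + NHW * c;
    const double* oc = op + NHW * c;
    const float* hc = xhp + NHW * c;
    double s1 = 0.0, s2 = 0.0;
    for (size_t i = 0; i < NHW; ++i) {
      const double d = oc[i] > 0.0 ? dyc[i] : 0.0;
      s1 += d;
      s2 += d * hc[i];
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double g = gamma[c], is = invstd[c];
    double* dxc = dxp + NHW * c;
    if (training) {
      const double m1 = s1 / NHW, m2 = s2 / NHW;
      for (size_t i = 0; i < NHW; ++i) {
        const double d = oc[i] > 0.0 ? dyc[i] : 0.0;
        dxc[i] = (d * g - m1 * g - hc[i] * m2 * g) * is;
      }
    } else {
      for (size_t i = 0; i < NHW; ++i) {
        const double d = oc[i] > 0.0 ? dyc[i] : 0.0;
        dxc[i] = d * g * is;
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
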