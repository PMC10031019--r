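// Convolution kernels backing the autodiff engine.
//
// Array conventions (column-major, as produced by R):
//   activations x : [H, W, C, N]
//   weights     w : [kh, kw, Cin, Cout]
//   bias        b : [Cout]
// im2col uses a (P x R) patch matrix with P = Ho*Wo output pixels and
// R = kh*kw*Cin patch entries, so that Y = cols * reshape(w) lands directly
// in the column-major layout of the output sample.

#include <RcppArmadillo.h>
using namespace Rcpp;

// pad_mode: 0 = zero padding, 1 = replicate (clamp) padding.  Replicate
// padding keeps constant inputs exactly constant, which matters because the
// instance-norm layers would otherwise amplify border artifacts.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

template <typename MAT>
static void col2im(const MAT& cols, double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int Ho, int Wo,
                   int pad_mode) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const auto* src = cols.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (pad_mode == 1) wi = clampi(wi, 0, W - 1);
          else if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (std::size_t)H * wi;
          const auto* s = src + (std::size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (pad_mode == 1) hi = clampi(hi, 0, H - 1);
            else if (hi < 0 || hi >= H) continue;
            xcol[hi] += s[ho];
          }
        }
      }
    }
  }
}

static IntegerVector dims_of(const NumericVector& a, int need) {
  if (!a.hasAttribute("dim"))
    stop("expected an array with a dim attribute");
  IntegerVector d = a.attr("dim");
  if (d.size() != need)
    stop("expected a %d-dimensional array, got %d dimensions", need, d.size());
  return d;
}

// Assemble the whole batch into one (N*P x R) patch matrix so a single GEMM
// serves all samples (thin per-sample GEMMs are slow for narrow layers).
template <typename MAT>
static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo, MAT& cols, int pad_mode) {
  const int P = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    // fill rows [n*P, (n+1)*P) of cols
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int r = i + kh * (j + kw * c);
          auto* dst = cols.colptr(r) + (std::size_t)P * n;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + j;
            auto* d = dst + (std::size_t)Ho * wo;
            if (wi < 0 || wi >= W) {
              if (pad_mode == 0) {
                for (int ho = 0; ho < Ho; ++ho) d[ho] = 0.0;
                continue;
              }
              wi = clampi(wi, 0, W - 1);
            }
            const double* src = xc + (std::size_t)H * wi;
            if (pad_mode == 1) {
              for (int ho = 0; ho < Ho; ++ho)
                d[ho] = src[clampi(ho * stride - pad + i, 0, H - 1)];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + i;
                d[ho] = (hi < 0 || hi >= H) ? 0.0 : src[hi];
              }
            }
          }
        }
      }
    }
  }
}

template <typename T>
static void conv2d_fwd_impl(const NumericVector& x, const NumericVector& w,
                            const NumericVector& b, int stride, int pad,
                            int pad_mode, int H, int W, int C, int N,
                            int kh, int kw, int Cout, int Ho, int Wo,
                            NumericVector& y) {
  const int P = Ho * Wo, R = kh * kw * C;
  arma::Mat<T> Wm(R, Cout);
  for (R_xlen_t i = 0; i < (R_xlen_t)R * Cout; ++i) Wm[i] = (T)w[i];
  arma::Mat<T> cols((std::size_t)P * N, R);
  im2col_batch(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, cols,
               pad_mode);
  arma::Mat<T> Y = cols * Wm;                    // (N*P) x Cout
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const T* src = Y.colptr(o) + (std::size_t)P * n;
      double* dst = y.begin() + (std::size_t)P * (o + (std::size_t)Cout * n);
      const double bo = b[o];
      for (int p = 0; p < P; ++p) dst[p] = (double)src[p] + bo;
    }
}

// single_prec selects float GEMM (training-grade, ~1.5x faster) or double
// (used by the finite-difference gradient checks).
// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int pad_mode, int single_prec) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: kernel larger than padded input");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  if (single_prec)
    conv2d_fwd_impl<float>(x, w, b, stride, pad, pad_mode, H, W, C, N,
                           kh, kw, Cout, Ho, Wo, y);
  else
    conv2d_fwd_impl<double>(x, w, b, stride, pad, pad_mode, H, W, C, N,
                            kh, kw, Cout, Ho, Wo, y);
  return y;
}

// gather gy ([Ho,Wo,Cout,N]) into (N*P x Cout)
template <typename T>
static arma::Mat<T> gy_to_mat(const double* gy, int P, int Cout, int N) {
  arma::Mat<T> GY((std::size_t)P * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* src = gy + (std::size_t)P * (o + (std::size_t)Cout * n);
      T* dst = GY.colptr(o) + (std::size_t)P * n;
      for (int p = 0; p < P; ++p) dst[p] = (T)src[p];
    }
  return GY;
}

template <typename T>
static void conv2d_bwd_data_impl(const NumericVector& gy,
                                 const NumericVector& w, int stride, int pad,
                                 int pad_mode, int H, int W, int Cin,
                                 int Cout, int N, int kh, int kw,
                                 int Ho, int Wo, NumericVector& gx) {
  const int P = Ho * Wo, R = kh * kw * Cin;
  arma::Mat<T> Wm(R, Cout);
  for (R_xlen_t i = 0; i < (R_xlen_t)R * Cout; ++i) Wm[i] = (T)w[i];
  arma::Mat<T> GY = gy_to_mat<T>(gy.begin(), P, Cout, N);
  arma::Mat<T> gcols = GY * Wm.t();              // (N*P) x R
  for (int n = 0; n < N; ++n) {
    arma::Mat<T> sub = gcols.rows((std::size_t)P * n,
                                  (std::size_t)P * n + P - 1);
    col2im(sub, gx.begin() + (std::size_t)H * W * Cin * n,
           H, W, Cin, kh, kw, stride, pad, Ho, Wo, pad_mode);
  }
}

// [[Rcpp::export(name = ".conv2d_bwd_data")]]
NumericVector conv2d_bwd_data(NumericVector gy, NumericVector w,
                              int stride, int pad, int H, int W,
                              int pad_mode, int single_prec) {
  IntegerVector gd = dims_of(gy, 4), wd = dims_of(w, 4);
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (Cout != wd[3]) stop("conv2d_bwd_data: channel mismatch");
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Cin * N));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  if (single_prec)
    conv2d_bwd_data_impl<float>(gy, w, stride, pad, pad_mode, H, W, Cin,
                                Cout, N, kh, kw, Ho, Wo, gx);
  else
    conv2d_bwd_data_impl<double>(gy, w, stride, pad, pad_mode, H, W, Cin,
                                 Cout, N, kh, kw, Ho, Wo, gx);
  return gx;
}

template <typename T>
static void conv2d_bwd_filter_impl(const NumericVector& x,
                                   const NumericVector& gy, int kh, int kw,
                                   int stride, int pad, int pad_mode,
                                   int H, int W, int C, int N, int Cout,
                                   int Ho, int Wo, NumericVector& gw,
                                   NumericVector& gb) {
  const int P = Ho * Wo, R = kh * kw * C;
  arma::Mat<T> cols((std::size_t)P * N, R);
  im2col_batch(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, cols,
               pad_mode);
  arma::Mat<T> GY = gy_to_mat<T>(gy.begin(), P, Cout, N);
  arma::Mat<T> GW = cols.t() * GY;
  for (R_xlen_t i = 0; i < (R_xlen_t)R * Cout; ++i) gw[i] = (double)GW[i];
  arma::Row<T> GB = arma::sum(GY, 0);
  for (int o = 0; o < Cout; ++o) gb[o] = (double)GB[o];
}

// [[Rcpp::export(name = ".conv2d_bwd_filter")]]
List conv2d_bwd_filter(NumericVector x, NumericVector gy,
                       int kh, int kw, int stride, int pad, int pad_mode,
                       int single_prec) {
  IntegerVector xd = dims_of(x, 4), gd = dims_of(gy, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  if (gd[3] != N) stop("conv2d_bwd_filter: batch mismatch");
  NumericVector gw(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C * Cout));
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector gb(Cout);
  if (single_prec)
    conv2d_bwd_filter_impl<float>(x, gy, kh, kw, stride, pad, pad_mode,
                                  H, W, C, N, Cout, Ho, Wo, gw, gb);
  else
    conv2d_bwd_filter_impl<double>(x, gy, kh, kw, stride, pad, pad_mode,
                                   H, W, C, N, Cout, Ho, Wo, gw, gb);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// ---- instance normalization -------------------------------------------------

// [[Rcpp::export(name = ".instnorm_fwd")]]
List instnorm_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                  double eps) {
  IntegerVector xd = dims_of(x, 4);
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = xd;
  NumericVector xhat(Rf_allocVector(REALSXP, x.size()));
  NumericVector inv(C * N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (std::size_t)HW * cn;
    double mu = 0.0;
    for (int i = 0; i < HW; ++i) mu += xs[i];
    mu /= HW;
    double var = 0.0;
    for (int i = 0; i < HW; ++i) { double d = xs[i] - mu; var += d * d; }
    var /= HW;
    const double iv = 1.0 / std::sqrt(var + eps);
    inv[cn] = iv;
    const double g = gamma[cn % C], b = beta[cn % C];
    double* xh = xhat.begin() + (std::size_t)HW * cn;
    double* yo = y.begin() + (std::size_t)HW * cn;
    for (int i = 0; i < HW; ++i) {
      xh[i] = (xs[i] - mu) * iv;
      yo[i] = g * xh[i] + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(name = ".instnorm_bwd")]]
List instnorm_bwd(NumericVector xhat, NumericVector inv, NumericVector gamma,
                  NumericVector g, IntegerVector dims) {
  const int HW = dims[0] * dims[1], C = dims[2], N = dims[3];
  NumericVector gx(Rf_allocVector(REALSXP, g.size()));
  gx.attr("dim") = dims;
  NumericVector ggamma(C), gbeta(C);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xh = xhat.begin() + (std::size_t)HW * cn;
    const double* gs = g.begin() + (std::size_t)HW * cn;
    const double gam = gamma[cn % C], iv = inv[cn];
    double m1 = 0.0, m2 = 0.0, sg = 0.0, sgx = 0.0;
    for (int i = 0; i < HW; ++i) {
      const double gh = gs[i] * gam;
      m1 += gh; m2 += gh * xh[i];
      sg += gs[i]; sgx += gs[i] * xh[i];
    }
    m1 /= HW; m2 /= HW;
    double* go = gx.begin() + (std::size_t)HW * cn;
    for (int i = 0; i < HW; ++i)
      go[i] = (gs[i] * gam - m1 - xh[i] * m2) * iv;
    ggamma[cn % C] += sgx;
    gbeta[cn % C] += sg;
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// ---- elementwise activations ------------------------------------------------
// type: 0 relu, 1 leaky relu, 2 sigmoid, 3 tanh

// [[Rcpp::export(name = ".act_fwd")]]
NumericVector act_fwd(NumericVector x, int type, double slope) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  if (x.hasAttribute("dim")) y.attr("dim") = x.attr("dim");
  const double* xs = x.begin(); double* ys = y.begin();
  const R_xlen_t n = x.size();
  switch (type) {
  case 0: for (R_xlen_t i = 0; i < n; ++i) ys[i] = xs[i] > 0 ? xs[i] : 0.0;
    break;
  case 1: for (R_xlen_t i = 0; i < n; ++i)
      ys[i] = xs[i] > 0 ? xs[i] : slope * xs[i];
    break;
  case 2: for (R_xlen_t i = 0; i < n; ++i) ys[i] = 1.0 / (1.0 + std::exp(-xs[i]));
    break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) ys[i] = std::tanh(xs[i]);
    break;
  default: stop("unknown activation");
  }
  return y;
}

// relu/lrelu take the input x as `ref`; sigmoid/tanh take the output y.
// [[Rcpp::export(name = ".act_bwd")]]
NumericVector act_bwd(NumericVector ref, NumericVector g, int type,
                      double slope) {
  NumericVector gx(Rf_allocVector(REALSXP, g.size()));
  if (g.hasAttribute("dim")) gx.attr("dim") = g.attr("dim");
  const double* r = ref.begin(); const double* gs = g.begin();
  double* go = gx.begin();
  const R_xlen_t n = g.size();
  switch (type) {
  case 0: for (R_xlen_t i = 0; i < n; ++i) go[i] = r[i] > 0 ? gs[i] : 0.0;
    break;
  case 1: for (R_xlen_t i = 0; i < n; ++i)
      go[i] = r[i] > 0 ? gs[i] : slope * gs[i];
    break;
  case 2: for (R_xlen_t i = 0; i < n; ++i) go[i] = gs[i] * r[i] * (1.0 - r[i]);
    break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) go[i] = gs[i] * (1.0 - r[i] * r[i]);
    break;
  default: stop("unknown activation");
  }
  return gx;
}
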