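// Convolution primitives for the VAE / U-Net / classifier stacks.
//
// Array layout conventions (column-major, as R stores them):
//   activations: (H, W, C, N)
//   conv weights: (kh, kw, Cin, Cout)
//   transposed-conv weights: (kh, kw, Cout, Cin)
// Convolutions are computed as im2col + GEMM; transposed convolutions are the
// exact adjoint (col2im of a GEMM), so convt_fwd/conv_bwd share kernels.
// Batches are processed in sample chunks to bound the col-buffer memory.
// A float32 compute path (use_float = true, the training default) performs
// the packing and GEMM in single precision inside a double-precision API;
// the double path is kept for exact finite-difference verification.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double COL_BUDGET_DOUBLES = 6.0e6; // ~48 MB col buffer cap

// Fill col (K x Ho*Wo*nc) from x chunk; K = kh*kw*C. Valid kernel ranges are
// precomputed per output position; interior positions take a branch-free
// contiguous-copy fast path.
template <typename T>
static void im2col_chunk(const double* x, int H, int W, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw,
                         int Ho, int Wo, int nc, T* col) {
  const int K = kh * kw * C;
  const long planeHW = (long)H * W;
  const long planeIn = planeHW * C;
  std::vector<int> ki_lo(Ho), ki_hi(Ho), kj_lo(Wo), kj_hi(Wo);
  for (int oh = 0; oh < Ho; ++oh) {
    int base = oh * sh - ph;
    ki_lo[oh] = std::max(0, -base);
    ki_hi[oh] = std::min(kh - 1, H - 1 - base);
  }
  for (int ow = 0; ow < Wo; ++ow) {
    int base = ow * sw - pw;
    kj_lo[ow] = std::max(0, -base);
    kj_hi[ow] = std::min(kw - 1, W - 1 - base);
  }
  for (int n = 0; n < nc; ++n) {
    const double* xn = x + (long)n * planeIn;
    for (int ow = 0; ow < Wo; ++ow) {
      const int jlo = kj_lo[ow], jhi = kj_hi[ow];
      const int iwbase = ow * sw - pw;
      const bool wfull = (jlo == 0 && jhi == kw - 1);
      for (int oh = 0; oh < Ho; ++oh) {
        T* cm = col + ((long)n * Ho * Wo + (long)ow * Ho + oh) * K;
        const int ilo = ki_lo[oh], ihi = ki_hi[oh];
        const int ihbase = oh * sh - ph;
        if (wfull && ilo == 0 && ihi == kh - 1) { // interior fast path
          for (int c = 0; c < C; ++c) {
            const double* xc = xn + (long)c * planeHW + (long)iwbase * H + ihbase;
            T* cmc = cm + kh * kw * c;
            for (int kj = 0; kj < kw; ++kj) {
              const double* xcol = xc + (long)kj * H;
              T* crow = cmc + kh * kj;
              for (int ki = 0; ki < kh; ++ki) crow[ki] = (T)xcol[ki];
            }
          }
        } else {
          std::fill(cm, cm + K, (T)0);
          for (int c = 0; c < C; ++c) {
            const double* xc = xn + (long)c * planeHW;
            T* cmc = cm + kh * kw * c;
            for (int kj = jlo; kj <= jhi; ++kj) {
              const double* xcol = xc + (long)(iwbase + kj) * H + ihbase;
              T* crow = cmc + kh * kj;
              for (int ki = ilo; ki <= ihi; ++ki) crow[ki] = (T)xcol[ki];
            }
          }
        }
      }
    }
  }
}

// Scatter-add col back into an accumulator chunk (adjoint of im2col)
template <typename T>
static void col2im_chunk(const T* col, int H, int W, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw,
                         int Ho, int Wo, int nc, T* x) {
  const int K = kh * kw * C;
  const long planeHW = (long)H * W;
  const long planeIn = planeHW * C;
  std::vector<int> ki_lo(Ho), ki_hi(Ho), kj_lo(Wo), kj_hi(Wo);
  for (int oh = 0; oh < Ho; ++oh) {
    int base = oh * sh - ph;
    ki_lo[oh] = std::max(0, -base);
    ki_hi[oh] = std::min(kh - 1, H - 1 - base);
  }
  for (int ow = 0; ow < Wo; ++ow) {
    int base = ow * sw - pw;
    kj_lo[ow] = std::max(0, -base);
    kj_hi[ow] = std::min(kw - 1, W - 1 - base);
  }
  for (int n = 0; n < nc; ++n) {
    T* xn = x + (long)n * planeIn;
    for (int ow = 0; ow < Wo; ++ow) {
      const int jlo = kj_lo[ow], jhi = kj_hi[ow];
      const int iwbase = ow * sw - pw;
      for (int oh = 0; oh < Ho; ++oh) {
        const T* cm = col + ((long)n * Ho * Wo + (long)ow * Ho + oh) * K;
        const int ilo = ki_lo[oh], ihi = ki_hi[oh];
        const int ihbase = oh * sh - ph;
        for (int c = 0; c < C; ++c) {
          T* xc = xn + (long)c * planeHW;
          const T* cmc = cm + kh * kw * c;
          for (int kj = jlo; kj <= jhi; ++kj) {
            T* xcol = xc + (long)(iwbase + kj) * H + ihbase;
            const T* crow = cmc + kh * kj;
            for (int ki = ilo; ki <= ihi; ++ki) xcol[ki] += crow[ki];
          }
        }
      }
    }
  }
}

static int chunk_size(int K, long HoWo, int N) {
  int nc = (int)(COL_BUDGET_DOUBLES / ((double)K * (double)HoWo));
  if (nc < 1) nc = 1;
  if (nc > N) nc = N;
  return nc;
}

static inline int out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

template <typename T> struct arma_types;
template <> struct arma_types<double> { typedef arma::mat mat; typedef arma::Col<double> vec; };
template <> struct arma_types<float> { typedef arma::fmat mat; typedef arma::Col<float> vec; };

template <typename T>
static void conv_fwd_core(const double* x, const int* xdim,
                          const double* w, const int* wdim,
                          const double* bias, int sh, int sw, int ph, int pw,
                          double* out) {
  typedef typename arma_types<T>::mat Tmat;
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = out_dim(H, kh, sh, ph), Wo = out_dim(W, kw, sw, pw);
  const int K = kh * kw * C;
  const long HoWo = (long)Ho * Wo;
  Tmat W2(K, Cout);
  for (long i = 0; i < (long)K * Cout; ++i) W2.memptr()[i] = (T)w[i];
  const int nc0 = chunk_size(K, HoWo, N);
  Tmat col(K, (long)HoWo * nc0);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    int nc = std::min(nc0, N - n0);
    im2col_chunk<T>(x + (long)n0 * H * W * C, H, W, C,
                    kh, kw, sh, sw, ph, pw, Ho, Wo, nc, col.memptr());
    Tmat colv(col.memptr(), K, HoWo * nc, false, true);
    Tmat o = colv.t() * W2; // (HoWo*nc) x Cout
    for (int n = 0; n < nc; ++n)
      for (int co = 0; co < Cout; ++co) {
        double b = bias[co];
        const T* src = o.colptr(co) + (long)n * HoWo;
        double* dst = out + ((long)(n0 + n) * Cout + co) * HoWo;
        for (long i = 0; i < HoWo; ++i) dst[i] = (double)src[i] + b;
      }
  }
}

template <typename T>
static void conv_bwd_core(const double* x, const int* xdim,
                          const double* w, const int* wdim,
                          const double* gout, int sh, int sw, int ph, int pw,
                          bool need_dx, double* dx, double* dwv, double* dbv) {
  typedef typename arma_types<T>::mat Tmat;
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = out_dim(H, kh, sh, ph), Wo = out_dim(W, kw, sw, pw);
  const int K = kh * kw * C;
  const long HoWo = (long)Ho * Wo;
  Tmat W2(K, Cout);
  for (long i = 0; i < (long)K * Cout; ++i) W2.memptr()[i] = (T)w[i];
  Tmat dW2(K, Cout, arma::fill::zeros);
  typename arma_types<T>::vec db(Cout, arma::fill::zeros);
  std::vector<T> dxbuf;
  if (need_dx) dxbuf.assign((long)H * W * C * N, (T)0);
  const int nc0 = chunk_size(K, HoWo, N);
  Tmat col(K, (long)HoWo * nc0);
  Tmat g(HoWo * (long)nc0, Cout);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    int nc = std::min(nc0, N - n0);
    im2col_chunk<T>(x + (long)n0 * H * W * C, H, W, C,
                    kh, kw, sh, sw, ph, pw, Ho, Wo, nc, col.memptr());
    Tmat colv(col.memptr(), K, HoWo * nc, false, true);
    Tmat gv(g.memptr(), HoWo * nc, Cout, false, true);
    for (int n = 0; n < nc; ++n)
      for (int co = 0; co < Cout; ++co) {
        const double* src = gout + ((long)(n0 + n) * Cout + co) * HoWo;
        T* dst = gv.colptr(co) + (long)n * HoWo;
        for (long i = 0; i < HoWo; ++i) dst[i] = (T)src[i];
      }
    dW2 += colv * gv;
    db += arma::sum(gv, 0).t();
    if (need_dx) {
      Tmat dcol = W2 * gv.t(); // K x (HoWo*nc)
      col2im_chunk<T>(dcol.memptr(), H, W, C, kh, kw, sh, sw, ph, pw,
                      Ho, Wo, nc, dxbuf.data() + (long)n0 * H * W * C);
    }
  }
  if (need_dx) {
    const long n = (long)H * W * C * N;
    for (long i = 0; i < n; ++i) dx[i] = (double)dxbuf[i];
  }
  for (long i = 0; i < (long)K * Cout; ++i) dwv[i] = (double)dW2.memptr()[i];
  for (int co = 0; co < Cout; ++co) dbv[co] = (double)db[co];
}

template <typename T>
static void convt_fwd_core(const double* x, const int* xdim,
                           const double* w, const int* wdim,
                           const double* bias, int sh, int sw, int ph, int pw,
                           double* out) {
  typedef typename arma_types<T>::mat Tmat;
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[2];
  const int Ho = (H - 1) * sh - 2 * ph + kh, Wo = (W - 1) * sw - 2 * pw + kw;
  const int K = kh * kw * Cout;
  const long HW = (long)H * W;
  const long HoWo = (long)Ho * Wo;
  Tmat W2(K, Cin);
  for (long i = 0; i < (long)K * Cin; ++i) W2.memptr()[i] = (T)w[i];
  std::vector<T> obuf((long)HoWo * Cout * N, (T)0);
  const int nc0 = chunk_size(K, HW, N);
  Tmat xm(HW * (long)nc0, Cin);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    int nc = std::min(nc0, N - n0);
    Tmat xv(xm.memptr(), HW * nc, Cin, false, true);
    for (int n = 0; n < nc; ++n)
      for (int c = 0; c < Cin; ++c) {
        const double* src = x + ((long)(n0 + n) * Cin + c) * HW;
        T* dst = xv.colptr(c) + (long)n * HW;
        for (long i = 0; i < HW; ++i) dst[i] = (T)src[i];
      }
    Tmat dcol = W2 * xv.t(); // K x (HW*nc)
    col2im_chunk<T>(dcol.memptr(), Ho, Wo, Cout, kh, kw, sh, sw, ph, pw,
                    H, W, nc, obuf.data() + (long)n0 * HoWo * Cout);
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double b = bias[co];
      const T* src = obuf.data() + ((long)n * Cout + co) * HoWo;
      double* dst = out + ((long)n * Cout + co) * HoWo;
      for (long i = 0; i < HoWo; ++i) dst[i] = (double)src[i] + b;
    }
}

template <typename T>
static void convt_bwd_core(const double* x, const int* xdim,
                           const double* w, const int* wdim,
                           const double* gout, int sh, int sw, int ph, int pw,
                           bool need_dx, double* dx, double* dwv, double* dbv) {
  typedef typename arma_types<T>::mat Tmat;
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[2];
  const int Ho = (H - 1) * sh - 2 * ph + kh, Wo = (W - 1) * sw - 2 * pw + kw;
  const int K = kh * kw * Cout;
  const long HW = (long)H * W;
  const long HoWo = (long)Ho * Wo;
  Tmat W2(K, Cin);
  for (long i = 0; i < (long)K * Cin; ++i) W2.memptr()[i] = (T)w[i];
  Tmat dW2(K, Cin, arma::fill::zeros);
  const int nc0 = chunk_size(K, HW, N);
  Tmat col(K, HW * (long)nc0);
  Tmat xm(HW * (long)nc0, Cin);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    int nc = std::min(nc0, N - n0);
    im2col_chunk<T>(gout + (long)n0 * HoWo * Cout, Ho, Wo, Cout,
                    kh, kw, sh, sw, ph, pw, H, W, nc, col.memptr());
    Tmat colv(col.memptr(), K, HW * nc, false, true);
    Tmat xv(xm.memptr(), HW * nc, Cin, false, true);
    for (int n = 0; n < nc; ++n)
      for (int c = 0; c < Cin; ++c) {
        const double* src = x + ((long)(n0 + n) * Cin + c) * HW;
        T* dst = xv.colptr(c) + (long)n * HW;
        for (long i = 0; i < HW; ++i) dst[i] = (T)src[i];
      }
    dW2 += colv * xv;
    if (need_dx) {
      Tmat dxm = colv.t() * W2; // (HW*nc) x Cin
      for (int n = 0; n < nc; ++n)
        for (int c = 0; c < Cin; ++c) {
          const T* s2 = dxm.colptr(c) + (long)n * HW;
          double* dst = dx + ((long)(n0 + n) * Cin + c) * HW;
          for (long i = 0; i < HW; ++i) dst[i] = (double)s2[i];
        }
    }
  }
  for (long i = 0; i < (long)K * Cin; ++i) dwv[i] = (double)dW2.memptr()[i];
  for (int co = 0; co < Cout; ++co) {
    double acc = 0;
    for (int n = 0; n < N; ++n) {
      const double* g = gout + ((long)n * Cout + co) * HoWo;
      for (long i = 0; i < HoWo; ++i) acc += g[i];
    }
    dbv[co] = acc;
  }
}

// [[Rcpp::export]]
NumericVector cc_conv_fwd(NumericVector x, IntegerVector xdim,
                          NumericVector w, IntegerVector wdim,
                          NumericVector bias,
                          IntegerVector stride, IntegerVector pad,
                          bool use_float = true) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv: channel mismatch");
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int Ho = out_dim(H, kh, sh, ph), Wo = out_dim(W, kw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("conv: non-positive output size");
  NumericVector out((long)Ho * Wo * Cout * N);
  if (use_float)
    conv_fwd_core<float>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                         bias.begin(), sh, sw, ph, pw, out.begin());
  else
    conv_fwd_core<double>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                          bias.begin(), sh, sw, ph, pw, out.begin());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cc_conv_bwd(NumericVector x, IntegerVector xdim,
                 NumericVector w, IntegerVector wdim,
                 NumericVector gout,
                 IntegerVector stride, IntegerVector pad,
                 bool need_dx = true, bool use_float = true) {
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  NumericVector dx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  NumericVector dwv((long)kh * kw * Cin * Cout);
  NumericVector dbv(Cout);
  if (use_float)
    conv_bwd_core<float>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                         gout.begin(), sh, sw, ph, pw, need_dx,
                         dx.begin(), dwv.begin(), dbv.begin());
  else
    conv_bwd_core<double>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                          gout.begin(), sh, sw, ph, pw, need_dx,
                          dx.begin(), dwv.begin(), dbv.begin());
  dx.attr("dim") = xdim;
  dwv.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// Transposed conv: out dims Ho = (H-1)*sh - 2*ph + kh
// [[Rcpp::export]]
NumericVector cc_convt_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, IntegerVector wdim,
                           NumericVector bias,
                           IntegerVector stride, IntegerVector pad,
                           bool use_float = true) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[2], Cw = wdim[3];
  if (Cw != Cin) stop("convt: channel mismatch");
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int Ho = (H - 1) * sh - 2 * ph + kh, Wo = (W - 1) * sw - 2 * pw + kw;
  if (Ho < 1 || Wo < 1) stop("convt: non-positive output size");
  NumericVector out((long)Ho * Wo * Cout * N);
  if (use_float)
    convt_fwd_core<float>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                          bias.begin(), sh, sw, ph, pw, out.begin());
  else
    convt_fwd_core<double>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                           bias.begin(), sh, sw, ph, pw, out.begin());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cc_convt_bwd(NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector wdim,
                  NumericVector gout,
                  IntegerVector stride, IntegerVector pad,
                  bool need_dx = true, bool use_float = true) {
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[2], Cin = wdim[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  NumericVector dx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  NumericVector dwv((long)kh * kw * Cout * Cin);
  NumericVector dbv(Cout);
  if (use_float)
    convt_bwd_core<float>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                          gout.begin(), sh, sw, ph, pw, need_dx,
                          dx.begin(), dwv.begin(), dbv.begin());
  else
    convt_bwd_core<double>(x.begin(), xdim.begin(), w.begin(), wdim.begin(),
                           gout.begin(), sh, sw, ph, pw, need_dx,
                           dx.begin(), dwv.begin(), dbv.begin());
  dx.attr("dim") = xdim;
  dwv.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// y[i] = x[i] * mult[b] + add[b], b = i / block  (block-wise affine; covers
// batch-norm, group-norm and per-channel embedding broadcasts)
// [[Rcpp::export]]
NumericVector cc_block_affine(NumericVector x, int block,
                              NumericVector mult, NumericVector add) {
  long n = x.size();
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  long nb = mult.size();
  long i = 0;
  for (long b = 0; b < nb; ++b) {
    double m = mult[b], a = add[b];
    for (int k = 0; k < block; ++k, ++i) yp[i] = xp[i] * m + a;
  }
  if (i != n) stop("block_affine: size mismatch");
  y.attr("dim") = x.attr("dim");
  return y;
}

// per-block sum and sum of squares
// [[Rcpp::export]]
List cc_block_sum2(NumericVector x, int block) {
  long n = x.size();
  long nb = n / block;
  NumericVector s(nb), s2(nb);
  const double* xp = x.begin();
  long i = 0;
  for (long b = 0; b < nb; ++b) {
    double a = 0, a2 = 0;
    for (int k = 0; k < block; ++k, ++i) { a += xp[i]; a2 += xp[i] * xp[i]; }
    s[b] = a; s2[b] = a2;
  }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// per-block sum of x*y
// [[Rcpp::export]]
NumericVector cc_block_dot(NumericVector x, NumericVector y, int block) {
  long n = x.size();
  long nb = n / block;
  NumericVector s(nb);
  const double* xp = x.begin();
  const double* yp = y.begin();
  long i = 0;
  for (long b = 0; b < nb; ++b) {
    double a = 0;
    for (int k = 0; k < block; ++k, ++i) a += xp[i] * yp[i];
    s[b] = a;
  }
  return s;
}

// y[i] = v[i / block]  (block-wise expansion; adjoint of cc_block_sum2$sum)
// [[Rcpp::export]]
NumericVector cc_block_expand(NumericVector v, int block) {
  long nb = v.size();
  NumericVector y(nb * (long)block);
  double* yp = y.begin();
  long i = 0;
  for (long b = 0; b < nb; ++b) {
    double val = v[b];
    for (int k = 0; k < block; ++k, ++i) yp[i] = val;
  }
  return y;
}


// LeakyReLU forward/backward (single pass, no R temporaries)
// [[Rcpp::export]]
NumericVector cc_lrelu_fwd(NumericVector x, double slope) {
  long n = x.size();
  NumericVector y(n);
  const double* xp = x.begin(); double* yp = y.begin();
  for (long i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cc_lrelu_bwd(NumericVector x, NumericVector gy, double slope) {
  long n = x.size();
  NumericVector g(n);
  const double* xp = x.begin(); const double* gp = gy.begin();
  double* op = g.begin();
  for (long i = 0; i < n; ++i) op[i] = xp[i] > 0 ? gp[i] : slope * gp[i];
  g.attr("dim") = gy.attr("dim");
  return g;
}

// In-place Adam update: p -= lr * (m/bc1) / (sqrt(v/bc2) + eps)
// [[Rcpp::export]]
void cc_adam_update(NumericVector p, NumericVector g,
                    NumericVector m, NumericVector v,
                    double lr, double beta1, double beta2,
                    double eps, int t) {
  long n = p.size();
  double bc1 = 1 - std::pow(beta1, t);
  double bc2 = 1 - std::pow(beta2, t);
  double* pp = p.begin(); const double* gp = g.begin();
  double* mp = m.begin(); double* vp = v.begin();
  for (long i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}

// In-place EMA: e = decay * e + (1 - decay) * p
// [[Rcpp::export]]
void cc_ema_update(NumericVector e, NumericVector p, double decay) {
  long n = e.size();
  double* ep = e.begin(); const double* pp = p.begin();
  for (long i = 0; i < n; ++i) ep[i] = decay * ep[i] + (1 - decay) * pp[i];
}

// In-place helpers for the training loop's gradient buffers
// [[Rcpp::export]]
void cc_fill0(NumericVector x) {
  std::fill(x.begin(), x.end(), 0.0);
}

// [[Rcpp::export]]
void cc_inplace_add(NumericVector target, NumericVector source) {
  long n = target.size();
  if (source.size() != n) stop("inplace_add: length mismatch");
  double* t = target.begin(); const double* s = source.begin();
  for (long i = 0; i < n; ++i) t[i] += s[i];
}
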