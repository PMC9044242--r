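// im2col / col2im kernels backing the convolution layers.
// Feature maps are stored as (H*W) x C matrices whose memory layout equals
// a column-major H x W x C array; columns of the unrolled matrix are
// ordered channel-major then kernel offset (kj fast over columns, ki over
// rows), matching the weight matrix layout (k*k*Cin) x Cout used in R.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// valid output range [lo, hi] for which in = out*stride + koff - pad
// stays inside [0, n)
static inline void validRange(int n, int nOut, int stride, int koff,
                              int pad, int& lo, int& hi) {
  int num = pad - koff;
  lo = num <= 0 ? 0 : (num + stride - 1) / stride;
  hi = (n - 1 - koff + pad) / stride;
  if (hi > nOut - 1) hi = nOut - 1;
}

// [[Rcpp::export]]
NumericMatrix conv_im2col(NumericVector x, int H, int W, int C,
                          int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[0] + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      int wlo, whi;
      validRange(W, Wo, stride, kj, pad, wlo, whi);
      for (int ki = 0; ki < k; ++ki) {
        int hlo, hhi;
        validRange(H, Ho, stride, ki, pad, hlo, hhi);
        int nrun = hhi - hlo + 1;
        if (nrun <= 0) continue;
        double* col = &out(0, c * k * k + kj * k + ki);
        for (int wo = wlo; wo <= whi; ++wo) {
          const double* src = xc + (size_t)(wo * stride + kj - pad) * H +
                              (hlo * stride + ki - pad);
          double* dst = col + (size_t)wo * Ho + hlo;
          if (stride == 1) {
            std::memcpy(dst, src, nrun * sizeof(double));
          } else {
            for (int r = 0; r < nrun; ++r) dst[r] = src[(size_t)r * stride];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector conv_col2im(NumericMatrix cols, int H, int W, int C,
                          int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    double* xc = &x[0] + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      int wlo, whi;
      validRange(W, Wo, stride, kj, pad, wlo, whi);
      for (int ki = 0; ki < k; ++ki) {
        int hlo, hhi;
        validRange(H, Ho, stride, ki, pad, hlo, hhi);
        int nrun = hhi - hlo + 1;
        if (nrun <= 0) continue;
        const double* col = &cols(0, c * k * k + kj * k + ki);
        for (int wo = wlo; wo <= whi; ++wo) {
          double* dst = xc + (size_t)(wo * stride + kj - pad) * H +
                        (hlo * stride + ki - pad);
          const double* src = col + (size_t)wo * Ho + hlo;
          if (stride == 1) {
            for (int r = 0; r < nrun; ++r) dst[r] += src[r];
          } else {
            for (int r = 0; r < nrun; ++r) dst[(size_t)r * stride] += src[r];
          }
        }
      }
    }
  }
  return x;
}

// fused per-channel (instance) normalization: one pass for statistics,
// one for outputs; avoids the large broadcast temporaries an R
// implementation needs
// [[Rcpp::export]]
List cpp_norm_fwd(NumericMatrix x, NumericVector gamma, NumericVector beta,
                  double eps) {
  int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C), xhat(n, C);
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double s = 0;
    for (int i = 0; i < n; ++i) s += xc[i];
    double mu = s / n, v = 0;
    for (int i = 0; i < n; ++i) { double d = xc[i] - mu; v += d * d; }
    double is = 1.0 / std::sqrt(v / n + eps);
    istd[c] = is;
    double g = gamma[c], b = beta[c];
    double* oc = &out(0, c); double* hc = &xhat(0, c);
    for (int i = 0; i < n; ++i) {
      double h = (xc[i] - mu) * is;
      hc[i] = h;
      oc[i] = g * h + b;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_norm_bwd(NumericMatrix dy, NumericMatrix xhat, NumericVector istd,
                  NumericVector gamma) {
  int n = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = &dy(0, c);
    const double* hc = &xhat(0, c);
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      sg += dc[i] * hc[i];
      sb += dc[i];
    }
    dgamma[c] = sg; dbeta[c] = sb;
    double g = gamma[c];
    s1 = g * sb; s2 = g * sg;
    double is = istd[c];
    double* xc = &dx(0, c);
    for (int i = 0; i < n; ++i)
      xc[i] = is * (g * dc[i] - s1 / n - hc[i] * s2 / n);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// out[, c] = m[, c] * v[c] (+ b[c] if given)
// [[Rcpp::export]]
NumericMatrix cpp_col_scale(NumericMatrix m, NumericVector v,
                            Nullable<NumericVector> shift = R_NilValue) {
  int n = m.nrow(), C = m.ncol();
  NumericMatrix out(n, C);
  NumericVector b = shift.isNotNull() ? NumericVector(shift)
                                      : NumericVector(C);
  for (int c = 0; c < C; ++c) {
    const double* mc = &m(0, c);
    double* oc = &out(0, c);
    double s = v[c], sb = b[c];
    for (int i = 0; i < n; ++i) oc[i] = mc[i] * s + sb;
  }
  return out;
}
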