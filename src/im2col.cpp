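#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for batched 2-D convolution.
// Input layout: [C, H, W, N] column-major (channel fastest).
// Output: matrix [C*k*k, Ho*Wo*N], column order: ho fastest, then wo, then n.
// "same"-style zero padding of pad pixels on each side.

// [[Rcpp::export]]
NumericMatrix im2col_nchw(NumericVector x, int C, int H, int W, int N,
                          int k, int stride, int pad, int dil = 1) {
  int keff = (k - 1) * dil + 1;
  int Ho = (H + 2 * pad - keff) / stride + 1;
  int Wo = (W + 2 * pad - keff) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int col = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho, ++col) {
        double* oc = op + (size_t)col * C * k * k;
        int h0 = ho * stride - pad, w0 = wo * stride - pad;
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw * dil;
          for (int kh = 0; kh < k; ++kh) {
            int h = h0 + kh * dil;
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double* src = xn + ((size_t)w * H + h) * C;
              for (int c = 0; c < C; ++c) oc[r++] = src[c];
            } else {
              for (int c = 0; c < C; ++c) oc[r++] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_nchw: scatter-add patch gradients back to image layout.
// [[Rcpp::export]]
NumericVector col2im_nchw(NumericMatrix cols, int C, int H, int W, int N,
                          int k, int stride, int pad, int dil = 1) {
  int keff = (k - 1) * dil + 1;
  int Ho = (H + 2 * pad - keff) / stride + 1;
  int Wo = (W + 2 * pad - keff) / stride + 1;
  NumericVector out((size_t)C * H * W * N);
  double* op = out.begin();
  const double* cp = cols.begin();
  int col = 0;
  for (int n = 0; n < N; ++n) {
    double* xn = op + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho, ++col) {
        const double* oc = cp + (size_t)col * C * k * k;
        int h0 = ho * stride - pad, w0 = wo * stride - pad;
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw * dil;
          for (int kh = 0; kh < k; ++kh) {
            int h = h0 + kh * dil;
            if (h >= 0 && h < H && w >= 0 && w < W) {
              double* dst = xn + ((size_t)w * H + h) * C;
              for (int c = 0; c < C; ++c) dst[c] += oc[r++];
            } else {
              r += C;
            }
          }
        }
      }
    }
  }
  return out;
}

// Mean-pool non-overlapping f x f blocks; layout [C,H,W,N] -> [C,H/f,W/f,N].
// [[Rcpp::export]]
NumericVector avgpool_nchw(NumericVector x, int C, int H, int W, int N, int f) {
  int Ho = H / f, Wo = W / f;
  NumericVector out((size_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  double inv = 1.0 / (f * f);
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * H * W;
    double* on = op + (size_t)n * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double* dst = on + ((size_t)wo * Ho + ho) * C;
        for (int kw = 0; kw < f; ++kw)
          for (int kh = 0; kh < f; ++kh) {
            const double* src = xn + ((size_t)(wo * f + kw) * H + ho * f + kh) * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        for (int c = 0; c < C; ++c) dst[c] *= inv;
      }
  }
  return out;
}
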