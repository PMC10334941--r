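#include <Rcpp.h>
using namespace Rcpp;

// Batch layout everywhere: (C, H, W, N), column-major, i.e. index
//   c + C*(h + H*(w + W*n))
// so the channel runs fastest.  Convolutions are done as one GEMM per
// batch on the im2col matrix; the GEMM itself happens in R via %*% so it
// uses the linked BLAS.

static inline int idx4(int c, int h, int w, int n, int C, int H, int W) {
  return c + C * (h + H * (w + W * n));
}

// im2col for a k x k kernel with symmetric zero padding and stride.
// Output: (C*k*k) x (Ho*Wo*N); column = ho + Ho*(wo + Wo*n),
// row = c + C*(ki + k*kj) with ki indexing kernel rows (h offset).
// [[Rcpp::export(name = ".nn_im2col")]]
NumericMatrix nn_im2col(NumericVector x, int C, int H, int W, int N,
                        int k, int pad, int stride) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo * N);
  const double *px = x.begin();
  double *po = out.begin();
  int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int col = ho + Ho * (wo + Wo * n);
        double *colp = po + (size_t)col * nrow;
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * stride - pad + ki;
            double *dst = colp + C * (ki + k * kj);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double *src = px + idx4(0, h, w, n, C, H, W);
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into the input gradient.
// [[Rcpp::export(name = ".nn_col2im")]]
NumericVector nn_col2im(NumericMatrix cols, int C, int H, int W, int N,
                        int k, int pad, int stride) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)C * H * W * N);
  double *po = out.begin();
  const double *pc = cols.begin();
  int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int col = ho + Ho * (wo + Wo * n);
        const double *colp = pc + (size_t)col * nrow;
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            const double *src = colp + C * (ki + k * kj);
            double *dst = po + idx4(0, h, w, n, C, H, W);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  return out;
}

// 2x2 max pooling (stride 2).  Returns pooled values and 1-based argmax
// linear indices into the input so the backward pass is a scatter.
// [[Rcpp::export(name = ".nn_maxpool")]]
List nn_maxpool(NumericVector x, int C, int H, int W, int N) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)C * Ho * Wo * N);
  IntegerVector arg((size_t)C * Ho * Wo * N);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          int best = idx4(c, 2 * ho, 2 * wo, n, C, H, W);
          double bv = px[best];
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              int i = idx4(c, 2 * ho + dh, 2 * wo + dw, n, C, H, W);
              if (px[i] > bv) { bv = px[i]; best = i; }
            }
          int o = idx4(c, ho, wo, n, C, Ho, Wo);
          y[o] = bv;
          arg[o] = best + 1;
        }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".nn_maxpool_bwd")]]
NumericVector nn_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                             int C, int H, int W, int N) {
  NumericVector dx((size_t)C * H * W * N);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}
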