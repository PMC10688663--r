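// Compiled convolution kernels.  Activations are H x W x C x N arrays in
// R's column-major layout, so for fixed (c, n) each spatial plane is a
// contiguous H x W block.  Same-size zero padding throughout; dilation `d`
// expands the tap offsets.

#include <Rcpp.h>
using namespace Rcpp;

// Depthwise 3x3 convolution, dilation d.  w has dims (3, 3, C).
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             int H, int W, int C, int N, int d) {
  NumericVector y(x.size());
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)n * C + c) * plane;
      double* yc = yp + ((R_xlen_t)n * C + c) * plane;
      const double* k = wp + (R_xlen_t)9 * c;  // (ti, tj) at ti + 3*tj
      for (int wc = 0; wc < W; ++wc) {
        for (int tj = 0; tj < 3; ++tj) {
          int sc = wc + (tj - 1) * d;
          if (sc < 0 || sc >= W) continue;
          const double* xcol = xc + (R_xlen_t)sc * H;
          double* ycol = yc + (R_xlen_t)wc * H;
          for (int ti = 0; ti < 3; ++ti) {
            const double kv = k[ti + 3 * tj];
            if (kv == 0.0) continue;
            const int off = (ti - 1) * d;
            const int h0 = std::max(0, -off), h1 = std::min(H, H - off);
            for (int h = h0; h < h1; ++h) ycol[h] += kv * xcol[h + off];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// Backward of the depthwise convolution: gradients w.r.t. input and kernel.
// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int H, int W, int C, int N, int d) {
  NumericVector gx(x.size());
  NumericVector gw((R_xlen_t)9 * C);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)n * C + c) * plane;
      const double* gc = gyp + ((R_xlen_t)n * C + c) * plane;
      double* gxc = gxp + ((R_xlen_t)n * C + c) * plane;
      const double* k = wp + (R_xlen_t)9 * c;
      double* gk = gwp + (R_xlen_t)9 * c;
      for (int wc = 0; wc < W; ++wc) {
        for (int tj = 0; tj < 3; ++tj) {
          int sc = wc + (tj - 1) * d;
          if (sc < 0 || sc >= W) continue;
          const double* xcol = xc + (R_xlen_t)sc * H;
          double* gxcol = gxc + (R_xlen_t)sc * H;
          const double* gcol = gc + (R_xlen_t)wc * H;
          for (int ti = 0; ti < 3; ++ti) {
            const double kv = k[ti + 3 * tj];
            const int off = (ti - 1) * d;
            const int h0 = std::max(0, -off), h1 = std::min(H, H - off);
            double acc = 0.0;
            for (int h = h0; h < h1; ++h) {
              const double g = gcol[h];
              acc += g * xcol[h + off];
              gxcol[h + off] += kv * g;
            }
            gk[ti + 3 * tj] += acc;
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(3, 3, C);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Generic dense KxK convolution (odd kernel, same zero padding, dilation d).
// w has dims (kh, kw, Ci, Co).
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             int H, int W, int Ci, int N,
                             int kh, int kw, int Co, int d) {
  NumericVector y((R_xlen_t)H * W * Co * N);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);
  const R_xlen_t plane = (R_xlen_t)H * W;
  const int ch = kh / 2, cw = kw / 2;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      double* yc = yp + ((R_xlen_t)n * Co + co) * plane;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc = xp + ((R_xlen_t)n * Ci + ci) * plane;
        const double* k = wp + (R_xlen_t)kh * kw * (ci + (R_xlen_t)Ci * co);
        for (int wc = 0; wc < W; ++wc) {
          for (int tj = 0; tj < kw; ++tj) {
            int sc = wc + (tj - cw) * d;
            if (sc < 0 || sc >= W) continue;
            const double* xcol = xc + (R_xlen_t)sc * H;
            double* ycol = yc + (R_xlen_t)wc * H;
            for (int ti = 0; ti < kh; ++ti) {
              const double kv = k[ti + kh * tj];
              if (kv == 0.0) continue;
              const int off = (ti - ch) * d;
              const int h0 = std::max(0, -off), h1 = std::min(H, H - off);
              for (int h = h0; h < h1; ++h) ycol[h] += kv * xcol[h + off];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  return y;
}

// Backward of the dense convolution.
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int H, int W, int Ci, int N,
                    int kh, int kw, int Co, int d) {
  NumericVector gx(x.size());
  NumericVector gw(w.size());
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gyp = REAL(gy);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  const R_xlen_t plane = (R_xlen_t)H * W;
  const int ch = kh / 2, cw = kw / 2;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* gc = gyp + ((R_xlen_t)n * Co + co) * plane;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc = xp + ((R_xlen_t)n * Ci + ci) * plane;
        double* gxc = gxp + ((R_xlen_t)n * Ci + ci) * plane;
        const double* k = wp + (R_xlen_t)kh * kw * (ci + (R_xlen_t)Ci * co);
        double* gk = gwp + (R_xlen_t)kh * kw * (ci + (R_xlen_t)Ci * co);
        for (int wc = 0; wc < W; ++wc) {
          for (int tj = 0; tj < kw; ++tj) {
            int sc = wc + (tj - cw) * d;
            if (sc < 0 || sc >= W) continue;
            const double* xcol = xc + (R_xlen_t)sc * H;
            double* gxcol = gxc + (R_xlen_t)sc * H;
            const double* gcol = gc + (R_xlen_t)wc * H;
            for (int ti = 0; ti < kh; ++ti) {
              const double kv = k[ti + kh * tj];
              const int off = (ti - ch) * d;
              const int h0 = std::max(0, -off), h1 = std::min(H, H - off);
              double acc = 0.0;
              for (int h = h0; h < h1; ++h) {
                const double g = gcol[h];
                acc += g * xcol[h + off];
                gxcol[h + off] += kv * g;
              }
              gk[ti + kh * tj] += acc;
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  gw.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Column-wise max and 1-based argmax (first occurrence) of an m x n matrix
// supplied as a flat vector.  Used by the attention reductions.
// [[Rcpp::export]]
List cpp_colmax(NumericVector x, int m, R_xlen_t n) {
  NumericVector mx(n);
  IntegerVector idx(n);
  const double* xp = REAL(x);
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* col = xp + j * m;
    double best = col[0];
    int bi = 0;
    for (int i = 1; i < m; ++i)
      if (col[i] > best) { best = col[i]; bi = i; }
    mx[j] = best;
    idx[j] = bi + 1;
  }
  return List::create(_["max"] = mx, _["idx"] = idx);
}

// ReLU forward / backward.
// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector gy) {
  NumericVector gx(y.size());
  const double* yp = REAL(y);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[i] = yp[i] > 0 ? gp[i] : 0.0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

// Batch-norm forward: normalize with given per-channel mean and inverse
// standard deviation, returning y and the normalized xhat.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mu, NumericVector ivar, int M, int C, int N) {
  NumericVector y(x.size()), xhat(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* hp = REAL(xhat);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * M;
      const double m = mu[c], iv = ivar[c], g = gamma[c], b = beta[c];
      for (int i = 0; i < M; ++i) {
        const double h = (xp[base + i] - m) * iv;
        hp[base + i] = h;
        yp[base + i] = g * h + b;
      }
    }
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Per-channel mean and (biased) variance over the (M, N) extent.
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, int M, int C, int N) {
  NumericVector mu(C), va(C);
  const double* xp = REAL(x);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * M;
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < M; ++i) {
        const double v = xp[base + i];
        s += v; s2 += v * v;
      }
      mu[c] += s; va[c] += s2;
    }
  const double nel = (double)M * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= nel;
    va[c] = std::max(va[c] / nel - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// Batch-norm backward (training mode uses the full batch-statistics
// Jacobian; inference mode only rescales).
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector xhat, NumericVector gy, NumericVector gamma,
                NumericVector ivar, int M, int C, int N, bool training) {
  NumericVector gx(xhat.size()), ggamma(C), gbeta(C);
  const double* hp = REAL(xhat);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * M;
      double a = 0.0, b = 0.0;
      for (int i = 0; i < M; ++i) {
        a += gp[base + i];
        b += gp[base + i] * hp[base + i];
      }
      s1[c] += a; s2[c] += b;
    }
  for (int c = 0; c < C; ++c) { gbeta[c] = s1[c]; ggamma[c] = s2[c]; }
  const double nel = (double)M * N;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * M;
      const double g = gamma[c], iv = ivar[c];
      if (training) {
        const double m1 = s1[c] * g / nel, m2 = s2[c] * g / nel;
        for (int i = 0; i < M; ++i)
          gxp[base + i] = (gp[base + i] * g - m1 - hp[base + i] * m2) * iv;
      } else {
        for (int i = 0; i < M; ++i) gxp[base + i] = gp[base + i] * g * iv;
      }
    }
  gx.attr("dim") = gy.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
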