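// Minimal CPU primitives for the internal conv-net engine.
// Tensor layout everywhere: column-major R arrays dim = (H, W, C, N).
// Weight layout: (k, k, Cin, Cout), so the flattened (k*k*Cin, Cout) matrix
// shares memory with the R array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;


static NumericVector num4d(int a, int b, int c, int d) {
  NumericVector v((std::size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector int4d(int a, int b, int c, int d) {
  IntegerVector v((std::size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col for one sample. x points at (H,W,Cin) block; col is (k*k*Cin, OH*OW).
static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, arma::mat& col) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int l = oh + OH * ow;
      double* dst = col.colptr(l);
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (std::size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            const int r = kh + k * (kw + k * c);
            dst[r] = (h >= 0 && h < H && w >= 0 && w < W)
                         ? xc[h + (std::size_t)H * w]
                         : 0.0;
          }
        }
      }
    }
  }
}

// col2im accumulation (transpose of im2col), for input gradients.
static void col2im(const arma::mat& col, int H, int W, int C, int k,
                   int stride, int pad, double* dx) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int l = oh + OH * ow;
      const double* src = col.colptr(l);
      const int h0 = oh * stride - pad;
      const int w0 = ow * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (std::size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            xc[h + (std::size_t)H * w] += src[kh + k * (kw + k * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int OH = out_size(H, k, stride, pad), OW = out_size(W, k, stride, pad);
  const int K = k * k * C, L = OH * OW;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y = num4d(OH, OW, Cout, N);
  arma::mat col(K, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride, pad,
           col);
    arma::mat Y = Wm.t() * col;  // (Cout, L)
    double* yp = y.begin() + (std::size_t)OH * OW * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      const double bc = b[c];
      for (int l = 0; l < L; ++l) yp[l + (std::size_t)L * c] = Y(c, l) + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy, int stride,
                int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int OH = out_size(H, k, stride, pad), OW = out_size(W, k, stride, pad);
  const int K = k * k * C, L = OH * OW;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx = num4d(H, W, C, N);
  NumericVector dw = num4d(k, k, C, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat col(K, L), dY(Cout, L);

  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (std::size_t)OH * OW * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (int l = 0; l < L; ++l) dY(c, l) = dyp[l + (std::size_t)L * c];
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride, pad,
           col);
    dWm += col * dY.t();
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dY.row(c));
    arma::mat dcol = Wm * dY;  // (K, L)
    col2im(dcol, H, W, C, k, stride, pad,
           dx.begin() + (std::size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling with stride 2 (floor on odd sizes). Returns pooled values
// plus the linear argmax offsets used by the backward pass.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int OH = H / 2, OW = W / 2;
  NumericVector y = num4d(OH, OW, C, N);
  IntegerVector idx = int4d(OH, OW, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)H * W * (c + (std::size_t)C * n);
      const double* xp = x.begin() + off;
      const std::size_t ooff =
          (std::size_t)OH * OW * (c + (std::size_t)C * n);
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -1e300;
          int bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2) {
            for (int dh = 0; dh < 2; ++dh) {
              const int h = 2 * oh + dh, w = 2 * ow + dw2;
              const int i = h + H * w;
              if (xp[i] > best) {
                best = xp[i];
                bi = i;
              }
            }
          }
          y[ooff + oh + (std::size_t)OH * ow] = best;
          idx[ooff + oh + (std::size_t)OH * ow] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int OH = yd[0], OW = yd[1], C = yd[2], N = yd[3];
  NumericVector dx = num4d(H, W, C, N);
  const std::size_t plane = (std::size_t)H * W, oplane = (std::size_t)OH * OW;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const std::size_t ooff = oplane * (c + (std::size_t)C * n);
      for (std::size_t l = 0; l < oplane; ++l)
        dx[off + idx[ooff + l]] += dy[ooff + l];
    }
  }
  return dx;
}
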