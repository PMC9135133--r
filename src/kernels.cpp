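// Convolution and max-pooling kernels for the scintigram classification
// network. Tensors cross the R/C++ boundary as column-major numeric arrays:
// feature maps are (H, W, C, N), convolution weights are (kh, kw, Cin, Cout).
// Convolution is im2col + GEMM; the column-row index r = ki + kh*(kj + kw*ci)
// must agree with the column-major flattening of the weight array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   arma::mat& col) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  col.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const double* plane = x + (std::size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          const double* src = plane + (std::size_t)j * H;
          double* dst = col.colptr(0) + r; // col is (K x L), stride K per column
          const std::size_t K = col.n_rows;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            dst[(std::size_t)(oi + Ho * oj) * K] = src[i];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   double* dx) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const std::size_t K = col.n_rows;
  for (int ci = 0; ci < C; ++ci) {
    double* plane = dx + (std::size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        const double* src = col.colptr(0) + r;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* dstp = plane + (std::size_t)j * H;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            dstp[i] += src[(std::size_t)(oi + Ho * oj) * K];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels, weights expect %d", C, Ci);
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int K = kh * kw * C;
  const std::size_t L = (std::size_t)Ho * Wo;

  NumericVector out(L * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Co, false, true);
  arma::mat col(K, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, col);
    arma::mat om(out.begin() + (std::size_t)n * L * Co, L, Co, false, true);
    om = col.t() * Wm;
    om.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                int stride, int pad, bool need_dx = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * C;
  const std::size_t L = (std::size_t)Ho * Wo;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Co);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat dWm(dw.begin(), K, Co, false, true);
  arma::rowvec dbv(db.begin(), Co, false, true);
  arma::mat col(K, L), dcol(K, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, col);
    arma::mat D(const_cast<double*>(dout.begin()) + (std::size_t)n * L * Co, L, Co, false, true);
    dWm += col * D;
    dbv += arma::sum(D, 0);
    if (need_dx) {
      dcol = Wm * D.t();
      col2im(dcol, H, W, C, kh, kw, stride, pad,
             dx.begin() + (std::size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("maxpool: output size would be empty");

  NumericVector out((std::size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(out.size()); // 1-based linear index into x (argmax)

  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          const int i0 = oi * stride, j0 = oj * stride;
          double best = xp[base + (std::size_t)j0 * H + i0];
          std::size_t bidx = base + (std::size_t)j0 * H + i0;
          for (int dj = 0; dj < k; ++dj) {
            const std::size_t coloff = base + (std::size_t)(j0 + dj) * H;
            for (int di = 0; di < k; ++di) {
              const double v = xp[coloff + i0 + di];
              if (v > best) { best = v; bidx = coloff + i0 + di; }
            }
          }
          // output written in (Ho,Wo) column-major for this (c,n)
          const std::size_t oo = (((std::size_t)n * C + c) * Wo + oj) * Ho + oi;
          op[oo] = best;
          ip[oo] = (int)(bidx + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector idx, IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dp = dx.begin();
  const double* gp = dout.begin();
  const int* ip = idx.begin();
  for (R_xlen_t t = 0; t < dout.size(); ++t) dp[ip[t] - 1] += gp[t];
  return dx;
}

// Fused Adam step: updates first/second moment buffers in place (they are
// owned exclusively by the optimizer closure) and returns the new parameter
// value; bc1/bc2 are the bias-correction factors 1 - beta^t. Decoupled
// weight decay is applied when wd > 0.
// [[Rcpp::export(name = ".adam_update")]]
NumericVector adam_update(NumericVector w, NumericVector g,
                          NumericVector m, NumericVector v,
                          double lr, double b1, double b2, double eps,
                          double bc1, double bc2, double wd) {
  const R_xlen_t n = w.size();
  NumericVector out(n);
  double* mp = m.begin(); double* vp = v.begin();
  const double* wp = w.begin(); const double* gp = g.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    op[i] = wp[i] - lr * ((mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps))
            - lr * wd * wp[i];
  }
  out.attr("dim") = w.attr("dim");
  return out;
}
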