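// Spatiotemporal layer primitives for the rPPG estimator.
//
// Tensors are R arrays with dim (C, T, H, W), column-major, so element
// (c,t,h,w) lives at c + C*(t + T*(h + H*w)) (0-based). 3-D convolution is
// implemented as per-timestep im2col + GEMM; the im2col row order is
// (c_in outer, then dt, dh, dw), which the R side mirrors when it lays out
// weight matrices of shape C_out x (C_in*kt*kh*kw). Temporal dilation applies
// to dt only; spatial dilation is always 1. Padding is zero and "same".

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long idx4(int c, int t, int h, int w, int C, int T, int H) {
  return c + (long)C * (t + (long)T * (h + (long)H * w));
}

static void im2col_t(const double* x, int C, int T, int H, int W,
                     int kt, int kh, int kw, int dil, int t_out,
                     arma::mat& col) {
  const int pt = dil * (kt - 1) / 2, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  int r = 0;
  for (int c = 0; c < C; ++c) {
    for (int dt = 0; dt < kt; ++dt) {
      const int t_in = t_out + dil * dt - pt;
      const bool t_ok = (t_in >= 0 && t_in < T);
      for (int dh = 0; dh < kh; ++dh) {
        for (int dw = 0; dw < kw; ++dw, ++r) {
          double* dst = col.colptr(0) + r;  // row r, advancing by n_rows
          const int K = col.n_rows;
          if (!t_ok) {
            for (int w = 0; w < W; ++w)
              for (int h = 0; h < H; ++h) { *dst = 0.0; dst += K; }
            continue;
          }
          for (int w = 0; w < W; ++w) {
            const int w_in = w + dw - pw;
            const bool w_ok = (w_in >= 0 && w_in < W);
            for (int h = 0; h < H; ++h) {
              const int h_in = h + dh - ph;
              double v = 0.0;
              if (w_ok && h_in >= 0 && h_in < H)
                v = x[idx4(c, t_in, h_in, w_in, C, T, H)];
              *dst = v; dst += K;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector dims,
                                 NumericMatrix wmat, NumericVector bias,
                                 int kt, int kh, int kw, int dil) {
  const int C = dims[0], T = dims[1], H = dims[2], W = dims[3];
  const int K = C * kt * kh * kw;
  const int Cout = wmat.nrow();
  if (wmat.ncol() != K) stop("conv3d: weight shape mismatch");
  arma::mat Wm(wmat.begin(), Cout, K, false);
  arma::vec b(bias.begin(), Cout, false);
  NumericVector y((long)Cout * T * H * W);
  arma::mat col(K, (long)H * W);
  for (int t = 0; t < T; ++t) {
    im2col_t(x.begin(), C, T, H, W, kt, kh, kw, dil, t, col);
    arma::mat out = Wm * col;            // Cout x (H*W)
    out.each_col() += b;
    // scatter into y at (.., t, h, w)
    const double* src = out.memptr();
    for (long j = 0; j < (long)H * W; ++j) {
      const int h = j % H, w = j / H;
      double* dst = REAL(y) + idx4(0, t, h, w, Cout, T, H);
      for (int c = 0; c < Cout; ++c) dst[c] = src[c + (long)Cout * j];
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, T, H, W);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, IntegerVector dims,
                         NumericMatrix wmat, NumericVector dy,
                         int kt, int kh, int kw, int dil, bool need_dx) {
  const int C = dims[0], T = dims[1], H = dims[2], W = dims[3];
  const int K = C * kt * kh * kw;
  const int Cout = wmat.nrow();
  arma::mat Wm(wmat.begin(), Cout, K, false);
  arma::mat dW(Cout, K, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : 1);
  arma::mat col(K, (long)H * W);
  arma::mat dYt(Cout, (long)H * W);
  const int pt = dil * (kt - 1) / 2, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int t = 0; t < T; ++t) {
    for (long j = 0; j < (long)H * W; ++j) {
      const int h = j % H, w = j / H;
      const double* src = REAL(dy) + idx4(0, t, h, w, Cout, T, H);
      for (int c = 0; c < Cout; ++c) dYt(c, j) = src[c];
    }
    im2col_t(x.begin(), C, T, H, W, kt, kh, kw, dil, t, col);
    dW += dYt * col.t();
    db += arma::sum(dYt, 1);
    if (need_dx) {
      arma::mat dcol = Wm.t() * dYt;     // K x (H*W)
      int r = 0;
      for (int c = 0; c < C; ++c)
        for (int dt = 0; dt < kt; ++dt) {
          const int t_in = t + dil * dt - pt;
          if (t_in < 0 || t_in >= T) { r += kh * kw; continue; }
          for (int dh = 0; dh < kh; ++dh)
            for (int dw = 0; dw < kw; ++dw, ++r) {
              for (int w2 = 0; w2 < W; ++w2) {
                const int w_in = w2 + dw - pw;
                if (w_in < 0 || w_in >= W) continue;
                for (int h2 = 0; h2 < H; ++h2) {
                  const int h_in = h2 + dh - ph;
                  if (h_in < 0 || h_in >= H) continue;
                  REAL(dx)[idx4(c, t_in, h_in, w_in, C, T, H)] +=
                      dcol(r, (long)h2 + (long)H * w2);
                }
              }
            }
        }
    }
  }
  if (need_dx) dx.attr("dim") = IntegerVector::create(C, T, H, W);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = wrap(db));
}

// Average pooling with clamped windows: output extent along each pooled
// dimension is ceil(in/stride); window o covers [o*s, o*s+k) intersected with
// the input, and the divisor is the actual cell count, so a kernel-2/stride-1
// temporal pool preserves length.
// [[Rcpp::export]]
NumericVector cpp_avgpool3d_forward(NumericVector x, IntegerVector dims,
                                    IntegerVector kernel, IntegerVector stride) {
  const int C = dims[0], T = dims[1], H = dims[2], W = dims[3];
  int kt = kernel[0], kh = kernel[1], kw = kernel[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  if (kh <= 0) kh = H;  // sentinel: global spatial pooling
  if (kw <= 0) kw = W;
  const int To = (kt >= T) ? 1 : (T + st - 1) / st;
  const int Ho = (kh >= H) ? 1 : (H + sh - 1) / sh;
  const int Wo = (kw >= W) ? 1 : (W + sw - 1) / sw;
  NumericVector y((long)C * To * Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * sw, w1 = std::min(W, w0 + kw);
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * sh, h1 = std::min(H, h0 + kh);
      for (int to = 0; to < To; ++to) {
        const int t0 = to * st, t1 = std::min(T, t0 + kt);
        const double inv = 1.0 / ((t1 - t0) * (h1 - h0) * (w1 - w0));
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h)
              for (int t = t0; t < t1; ++t)
                s += x[idx4(c, t, h, w, C, T, H)];
          y[idx4(c, to, ho, wo, C, To, Ho)] = s * inv;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, To, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3d_backward(NumericVector dy, IntegerVector in_dims,
                                     IntegerVector kernel, IntegerVector stride) {
  const int C = in_dims[0], T = in_dims[1], H = in_dims[2], W = in_dims[3];
  int kt = kernel[0], kh = kernel[1], kw = kernel[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  if (kh <= 0) kh = H;
  if (kw <= 0) kw = W;
  const int To = (kt >= T) ? 1 : (T + st - 1) / st;
  const int Ho = (kh >= H) ? 1 : (H + sh - 1) / sh;
  const int Wo = (kw >= W) ? 1 : (W + sw - 1) / sw;
  NumericVector dx((long)C * T * H * W);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * sw, w1 = std::min(W, w0 + kw);
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * sh, h1 = std::min(H, h0 + kh);
      for (int to = 0; to < To; ++to) {
        const int t0 = to * st, t1 = std::min(T, t0 + kt);
        const double inv = 1.0 / ((t1 - t0) * (h1 - h0) * (w1 - w0));
        for (int c = 0; c < C; ++c) {
          const double g = dy[idx4(c, to, ho, wo, C, To, Ho)] * inv;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h)
              for (int t = t0; t < t1; ++t)
                dx[idx4(c, t, h, w, C, T, H)] += g;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, T, H, W);
  return dx;
}

// Input gradient of same-padded odd-kernel correlation, computed as a
// forward correlation of dy with channel-transposed, tap-flipped weights
// (avoids the col2im scatter).
// [[Rcpp::export]]
NumericVector cpp_conv3d_dx(NumericVector dy, IntegerVector out_dims,
                            NumericMatrix wmat, int cin,
                            int kt, int kh, int kw, int dil) {
  const int Cout = out_dims[0], T = out_dims[1], H = out_dims[2], W = out_dims[3];
  arma::mat W2(cin, Cout * kt * kh * kw);
  for (int ci = 0; ci < cin; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int dt = 0; dt < kt; ++dt)
        for (int dh = 0; dh < kh; ++dh)
          for (int dw = 0; dw < kw; ++dw) {
            const int j2 = ((co * kt + dt) * kh + dh) * kw + dw;
            const int j1 = ((ci * kt + (kt - 1 - dt)) * kh + (kh - 1 - dh)) * kw
                           + (kw - 1 - dw);
            W2(ci, j2) = wmat(co, j1);
          }
  NumericVector dx((long)cin * T * H * W);
  arma::mat col(Cout * kt * kh * kw, (long)H * W);
  for (int t = 0; t < T; ++t) {
    im2col_t(dy.begin(), Cout, T, H, W, kt, kh, kw, dil, t, col);
    arma::mat out = W2 * col;
    const double* src = out.memptr();
    for (long j = 0; j < (long)H * W; ++j) {
      const int h = j % H, w = j / H;
      double* dst = REAL(dx) + idx4(0, t, h, w, cin, T, H);
      for (int c = 0; c < cin; ++c) dst[c] = src[c + (long)cin * j];
    }
  }
  dx.attr("dim") = IntegerVector::create(cin, T, H, W);
  return dx;
}
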