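// Minimal conv-net kernels: im2col convolution with full backward pass,
// 2x2 max pooling, nearest-neighbour upsampling, and a bilinear affine
// sampler shared by misalignment, rigid registration and in-plane resampling.
// Array layout follows R: column-major, dims (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Expand one (H,W,C) image into the (C*k*k) x (Ho*Wo) patch matrix.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  cols.set_size(C * k * k, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      int r = 0;
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          for (int kh = 0; kh < k; ++kh, ++r) {
            const int h = h0 + kh, w = w0 + kw;
            dst[r] = (h >= 0 && h < H && w >= 0 && w < W)
              ? x[h + H * (w + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter a patch matrix back onto the (H,W,C) grid (adjoint of im2col).
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int stride, int pad, double* x) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  std::fill(x, x + (size_t)H * W * C, 0.0);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double* src = cols.colptr(col);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      int r = 0;
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          for (int kh = 0; kh < k; ++kh, ++r) {
            const int h = h0 + kh, w = w0 + kw;
            if (h >= 0 && h < H && w >= 0 && w < W)
              x[h + H * (w + W * c)] += src[r];
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() == 3) { // promote (H,W,C) to batch of 1
    IntegerVector d4 = IntegerVector::create(d[0], d[1], d[2], 1);
    return d4;
  }
  if (d.size() != 4) stop("expected a (H,W,C,N) array");
  return d;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wts,
                             NumericVector bias, int stride, int pad) {
  IntegerVector dx = dims4(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  IntegerVector dw = wts.attr("dim"); // (k, k, Cin, Cout)
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != C) stop("weight dims do not match input channels");
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");

  arma::mat Wm(wts.begin(), (size_t)k * k * C, Cout, false, true); // (Ckk) x Cout
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    arma::mat out = Wm.t() * cols; // Cout x (Ho*Wo)
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c) {
      const double b = bias[c];
      for (int p = 0; p < Ho * Wo; ++p) yp[p + (size_t)Ho * Wo * c] = out(c, p) + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wts, NumericVector dy,
                    int stride, int pad) {
  IntegerVector dx_ = dims4(x);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  IntegerVector dw_ = wts.attr("dim");
  const int k = dw_[0], Cout = dw_[3];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);

  arma::mat Wm(wts.begin(), (size_t)k * k * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwts((size_t)k * k * C * Cout);
  dwts.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector dbias(Cout);
  arma::mat dWm(dwts.begin(), (size_t)k * k * C, Cout, false, true);

  arma::mat cols, dcols;
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
    arma::mat dY(Cout, Ho * Wo);
    for (int c = 0; c < Cout; ++c) {
      double acc = 0.0;
      for (int p = 0; p < Ho * Wo; ++p) {
        const double v = dyp[p + (size_t)Ho * Wo * c];
        dY(c, p) = v;
        acc += v;
      }
      dbias[c] += acc;
    }
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    dWm += cols * dY.t();
    dcols = Wm * dY; // (Ckk) x (Ho*Wo)
    col2im(dcols, H, W, C, k, stride, pad, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwts, _["db"] = dbias);
}

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int best = 2 * ho + H * (2 * wo);
          double bv = xp[best];
          const int cand[3] = {2 * ho + 1 + H * (2 * wo),
                               2 * ho + H * (2 * wo + 1),
                               2 * ho + 1 + H * (2 * wo + 1)};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          // column-major target index is ho + Ho*wo within the channel plane
          y[(size_t)Ho * Wo * (c + (size_t)C * n) + ho + Ho * wo] = bv;
          arg[(size_t)Ho * Wo * (c + (size_t)C * n) + ho + Ho * wo] = best;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                               IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const size_t off = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        dxp[argmax[off + p]] += dy[off + p];
    }
  return dx;
}

// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)4 * H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = xp[h + H * w];
          yp[2 * h + 2 * H * (2 * w)] = v;
          yp[2 * h + 1 + 2 * H * (2 * w)] = v;
          yp[2 * h + 2 * H * (2 * w + 1)] = v;
          yp[2 * h + 1 + 2 * H * (2 * w + 1)] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector d = dims4(dy);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          dxp[h + H * w] =
            dyp[2 * h + H2 * (2 * w)] + dyp[2 * h + 1 + H2 * (2 * w)] +
            dyp[2 * h + H2 * (2 * w + 1)] + dyp[2 * h + 1 + H2 * (2 * w + 1)];
    }
  return dx;
}

// Bilinear sampling of `img` (H x W matrix) at coordinates given by an affine
// map of the OUTPUT pixel grid: src = A %*% (r, c) + b, all 0-based row/col
// units. Out-of-bounds samples return `fill`.
// [[Rcpp::export(name = ".cpp_affine_sample")]]
NumericMatrix cpp_affine_sample(NumericMatrix img, NumericMatrix A,
                                NumericVector b, int out_h, int out_w,
                                double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  for (int c = 0; c < out_w; ++c)
    for (int r = 0; r < out_h; ++r) {
      const double sr = a11 * r + a12 * c + b[0];
      const double sc = a21 * r + a22 * c + b[1];
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const double fr = sr - r0, fc = sc - c0;
      double v = fill;
      if (r0 >= -1 && r0 <= H - 1 && c0 >= -1 && c0 <= W - 1) {
        auto px = [&](int rr, int cc) -> double {
          return (rr >= 0 && rr < H && cc >= 0 && cc < W) ? img(rr, cc) : fill;
        };
        v = (1 - fr) * (1 - fc) * px(r0, c0) + fr * (1 - fc) * px(r0 + 1, c0) +
            (1 - fr) * fc * px(r0, c0 + 1) + fr * fc * px(r0 + 1, c0 + 1);
      }
      out(r, c) = v;
    }
  return out;
}
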