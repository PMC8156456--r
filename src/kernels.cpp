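// Dense tensor kernels for the segmentation networks.
//
// Feature maps are column-major R arrays with dim c(H, W, C, N); weights for
// a 3x3 convolution have dim c(kh, kw, Cin, Cout).  Convolutions are stride-1
// with symmetric zero padding and are evaluated by im2col + BLAS gemm
// (via Armadillo).  Box sums use integral images with exact border clipping.
// Bilinear resampling uses half-pixel centers; its adjoint is used for
// backpropagation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int pad) { return in + 2 * pad - k + 1; }

// Build im2col matrix: K x (Ho*Wo) for one sample, K = kh*kw*Cin.
// Column index is ho + Ho*wo (column-major over output pixels); row index is
// dh + kh*(dw + kw*ci), matching the column-major flattening of the weight
// array c(kh, kw, Cin, Cout).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, double* cols) {
  const int Ho = out_dim(H, kh, pad), Wo = out_dim(W, kw, pad);
  const int K = kh * kw * C;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int row = dh + kh * (dw + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dw - pad;
          double* dst = cols + (size_t)row + (size_t)K * ((size_t)Wo * 0 + 0);
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              cols[(size_t)row + (size_t)K * (ho + (size_t)Ho * wo)] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + dh - pad;
            cols[(size_t)row + (size_t)K * (ho + (size_t)Ho * wo)] =
              (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add adjoint of im2col.
static void col2im(const double* cols, int H, int W, int C,
                   int kh, int kw, int pad, double* x) {
  const int Ho = out_dim(H, kh, pad), Wo = out_dim(W, kw, pad);
  const int K = kh * kw * C;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = x + (size_t)ci * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int row = dh + kh * (dw + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dw - pad;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + dh - pad;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += cols[(size_t)row + (size_t)K * (ho + (size_t)Ho * wo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = out_dim(H, kh, pad), Wo = out_dim(W, kw, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");
  const int K = kh * kw * C;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat cols(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad,
           cols.memptr());
    arma::mat ym(y.begin() + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    ym = cols.t() * Wm;
    for (int co = 0; co < Cout; ++co) ym.col(co) += bias[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad, bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_dim(H, kh, pad), Wo = out_dim(W, kw, pad);
  const int K = kh * kw * C;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat cols(K, (size_t)Ho * Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad,
           cols.memptr());
    dWm += cols * dym;
    if (need_dx) {
      arma::mat dcols = Wm * dym.t();          // K x (Ho*Wo)
      col2im(dcols.memptr(), H, W, C, kh, kw, pad,
             dx.begin() + (size_t)n * H * W * C);
    }
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dym.col(co));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pool, stride 2 (even H, W assumed; enforced by caller).
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  IntegerVector idx(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = xp + cn * H * W;
    double* ys = y.begin() + cn * Ho * Wo;
    int* is = idx.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = 2 * ho, w0 = 2 * wo;
        int best = h0 + H * w0;
        double bv = xs[best];
        const int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1),
                              h0 + 1 + H * (w0 + 1) };
        for (int t = 0; t < 3; ++t)
          if (xs[cand[t]] > bv) { bv = xs[cand[t]]; best = cand[t]; }
        ys[ho + Ho * wo] = bv;
        is[ho + Ho * wo] = best;   // index within the H*W slab
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* ds = dy.begin() + cn * Ho * Wo;
    const int* is = idx.begin() + cn * Ho * Wo;
    double* xs = dx.begin() + cn * H * W;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) xs[is[i]] += ds[i];
  }
  return dx;
}

// 2x2 average pool, stride 2.
// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = x.begin() + cn * H * W;
    double* ys = y.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = 2 * ho, w0 = 2 * wo;
        ys[ho + Ho * wo] = 0.25 * (xs[h0 + H * w0] + xs[h0 + 1 + H * w0] +
                                   xs[h0 + H * (w0 + 1)] +
                                   xs[h0 + 1 + H * (w0 + 1)]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_backward(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* ds = dy.begin() + cn * Ho * Wo;
    double* xs = dx.begin() + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * ds[ho + Ho * wo];
        const int h0 = 2 * ho, w0 = 2 * wo;
        xs[h0 + H * w0] += g;
        xs[h0 + 1 + H * w0] += g;
        xs[h0 + H * (w0 + 1)] += g;
        xs[h0 + 1 + H * (w0 + 1)] += g;
      }
  }
  return dx;
}

// Bilinear resize with half-pixel centers (the OpenCV / common deep-learning
// convention with align_corners = FALSE).
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0v(Ho), h1v(Ho), w0v(Wo), w1v(Wo);
  std::vector<double> fhv(Ho), fwv(Wo);
  for (int ho = 0; ho < Ho; ++ho) {
    double src = (ho + 0.5) * sh - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    int h0 = (int)std::floor(src);
    if (h0 > H - 2) h0 = H >= 2 ? H - 2 : 0;
    h0v[ho] = h0; h1v[ho] = H >= 2 ? h0 + 1 : 0; fhv[ho] = src - h0;
  }
  for (int wo = 0; wo < Wo; ++wo) {
    double src = (wo + 0.5) * sw - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    int w0 = (int)std::floor(src);
    if (w0 > W - 2) w0 = W >= 2 ? W - 2 : 0;
    w0v[wo] = w0; w1v[wo] = W >= 2 ? w0 + 1 : 0; fwv[wo] = src - w0;
  }
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = x.begin() + cn * H * W;
    double* ys = y.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double fw = fwv[wo];
      const double* c0 = xs + (size_t)w0v[wo] * H;
      const double* c1 = xs + (size_t)w1v[wo] * H;
      for (int ho = 0; ho < Ho; ++ho) {
        const double fh = fhv[ho];
        const double a = c0[h0v[ho]] * (1 - fh) + c0[h1v[ho]] * fh;
        const double b = c1[h0v[ho]] * (1 - fh) + c1[h1v[ho]] * fh;
        ys[ho + (size_t)Ho * wo] = a * (1 - fw) + b * fw;
      }
    }
  }
  return y;
}

// Adjoint of cpp_bilinear_resize: scatter dy (Ho x Wo) back to (H x W).
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize_backward(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0v(Ho), h1v(Ho), w0v(Wo), w1v(Wo);
  std::vector<double> fhv(Ho), fwv(Wo);
  for (int ho = 0; ho < Ho; ++ho) {
    double src = (ho + 0.5) * sh - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    int h0 = (int)std::floor(src);
    if (h0 > H - 2) h0 = H >= 2 ? H - 2 : 0;
    h0v[ho] = h0; h1v[ho] = H >= 2 ? h0 + 1 : 0; fhv[ho] = src - h0;
  }
  for (int wo = 0; wo < Wo; ++wo) {
    double src = (wo + 0.5) * sw - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    int w0 = (int)std::floor(src);
    if (w0 > W - 2) w0 = W >= 2 ? W - 2 : 0;
    w0v[wo] = w0; w1v[wo] = W >= 2 ? w0 + 1 : 0; fwv[wo] = src - w0;
  }
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* ds = dy.begin() + cn * Ho * Wo;
    double* xs = dx.begin() + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const double fw = fwv[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = ds[ho + (size_t)Ho * wo];
        const double fh = fhv[ho];
        xs[h0v[ho] + (size_t)w0v[wo] * H] += g * (1 - fh) * (1 - fw);
        xs[h1v[ho] + (size_t)w0v[wo] * H] += g * fh * (1 - fw);
        xs[h0v[ho] + (size_t)w1v[wo] * H] += g * (1 - fh) * fw;
        xs[h1v[ho] + (size_t)w1v[wo] * H] += g * fh * fw;
      }
    }
  }
  return dx;
}

// Sum of x over the (2r+1)^2 window centered at each pixel, clipped at the
// image border (He-style guided filter convention).  Integral image, O(N).
// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector x, int r) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  size_t slabs = 1;
  for (int i = 2; i < xd.size(); ++i) slabs *= xd[i];
  NumericVector y(Rcpp::no_init((size_t)H * W * slabs));
  y.attr("dim") = xd;
  std::vector<double> ii((size_t)(H + 1) * (W + 1));
  for (size_t s = 0; s < slabs; ++s) {
    const double* xs = x.begin() + s * H * W;
    double* ys = y.begin() + s * H * W;
    const int HI = H + 1;
    for (int h = 0; h <= H; ++h) ii[h] = 0.0;
    for (int w = 1; w <= W; ++w) {
      ii[(size_t)w * HI] = 0.0;
      double rowsum = 0.0;     // cumulative over h for this column
      for (int h = 1; h <= H; ++h) {
        rowsum += xs[(h - 1) + (size_t)(w - 1) * H];
        ii[h + (size_t)w * HI] = ii[h + (size_t)(w - 1) * HI] + rowsum;
      }
    }
    for (int w = 0; w < W; ++w) {
      const int w0 = std::max(0, w - r), w1 = std::min(W - 1, w + r);
      for (int h = 0; h < H; ++h) {
        const int h0 = std::max(0, h - r), h1 = std::min(H - 1, h + r);
        ys[h + (size_t)w * H] =
          ii[(h1 + 1) + (size_t)(w1 + 1) * HI] -
          ii[h0 + (size_t)(w1 + 1) * HI] -
          ii[(h1 + 1) + (size_t)w0 * HI] +
          ii[h0 + (size_t)w0 * HI];
      }
    }
  }
  return y;
}

// Fused batch-norm column ops on the (HW, C*N) matrix layout.
// Forward: xhat = (x - mu[c]) * istd[c];  y = xhat * gamma[c] + beta[c].
// [[Rcpp::export]]
List cpp_bn_forward(NumericMatrix x, NumericVector mu, NumericVector istd,
                    NumericVector gamma, NumericVector beta, int C) {
  const int M = x.nrow(), CN = x.ncol();
  NumericMatrix xhat(M, CN), y(M, CN);
  for (int j = 0; j < CN; ++j) {
    const int c = j % C;
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    const double* xs = &x(0, j);
    double* xh = &xhat(0, j);
    double* ys = &y(0, j);
    for (int i = 0; i < M; ++i) {
      const double v = (xs[i] - m) * is;
      xh[i] = v;
      ys[i] = v * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// Backward: returns dgamma/dbeta (per channel) and dx.
// training: dx = istd[c] * (dxhat - mean_c(dxhat) - xhat * mean_c(dxhat*xhat))
// where dxhat = dy * gamma[c] and means are over (HW, N) per channel.
// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dy, NumericMatrix xhat,
                     NumericVector gamma, NumericVector istd, int C,
                     bool training) {
  const int M = dy.nrow(), CN = dy.ncol();
  const int N = CN / C;
  NumericVector dgamma(C), dbeta(C), t1(C), t2(C);
  for (int j = 0; j < CN; ++j) {
    const int c = j % C;
    const double* ds = &dy(0, j);
    const double* xh = &xhat(0, j);
    double s1 = 0, s2 = 0;
    for (int i = 0; i < M; ++i) { s1 += ds[i]; s2 += ds[i] * xh[i]; }
    dbeta[c] += s1;
    dgamma[c] += s2;
  }
  const double inv = 1.0 / ((double)M * N);
  for (int c = 0; c < C; ++c) {
    t1[c] = dbeta[c] * inv * gamma[c];
    t2[c] = dgamma[c] * inv * gamma[c];
  }
  NumericMatrix dx(M, CN);
  for (int j = 0; j < CN; ++j) {
    const int c = j % C;
    const double g = gamma[c], is = istd[c];
    const double a = training ? t1[c] : 0.0, b = training ? t2[c] : 0.0;
    const double* ds = &dy(0, j);
    const double* xh = &xhat(0, j);
    double* dxs = &dx(0, j);
    for (int i = 0; i < M; ++i)
      dxs[i] = is * (ds[i] * g - a - xh[i] * b);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Per-channel mean/var over (HW, N) of the (HW, C*N) matrix.
// [[Rcpp::export]]
List cpp_bn_stats(NumericMatrix x, int C) {
  const int M = x.nrow(), CN = x.ncol();
  const int N = CN / C;
  NumericVector mu(C), va(C);
  for (int j = 0; j < CN; ++j) {
    const double* xs = &x(0, j);
    double s = 0;
    for (int i = 0; i < M; ++i) s += xs[i];
    mu[j % C] += s;
  }
  const double inv = 1.0 / ((double)M * N);
  for (int c = 0; c < C; ++c) mu[c] *= inv;
  for (int j = 0; j < CN; ++j) {
    const int c = j % C;
    const double m = mu[c];
    const double* xs = &x(0, j);
    double s = 0;
    for (int i = 0; i < M; ++i) { const double d = xs[i] - m; s += d * d; }
    va[c] += s;
  }
  for (int c = 0; c < C; ++c) va[c] *= inv;
  return List::create(_["mean"] = mu, _["var"] = va);
}
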