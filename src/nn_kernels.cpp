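// Low-level network primitives on (H, W, C) column-major arrays.
// Forward and backward passes are exact pairs: every backward kernel is the
// transpose of the linear map its forward kernel applies.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// im2col for a block of output pixels [q0, q1); rows index output pixels in
// column-major (ho fastest) order, columns index (kh, kw, cin) patch entries.
static void im2col_block(const double* x, int H, int W, int Cin,
                         int kh, int kw, int stride, int pad, int dil,
                         int Ho, int q0, int q1, arma::mat& P) {
  const int K = kh * kw * Cin;
  P.zeros(q1 - q0, K);
  const int nq = q1 - q0;
  for (int r = 0; r < K; ++r) {
    const int i = r % kh;
    const int j = (r / kh) % kw;
    const int ci = r / (kh * kw);
    const double* xc = x + (size_t)ci * H * W;
    double* pc = P.colptr(r);
    const int oh = dil * i - pad;   // hi = ho*stride + oh
    const int ow = dil * j - pad;
    int q = q0;
    while (q < q1) {
      const int wo = q / Ho;
      const int wi = wo * stride + ow;
      int ho = q - wo * Ho;
      const int row_end = std::min(q1, (wo + 1) * Ho);
      if (wi < 0 || wi >= W) { q = row_end; continue; }
      const double* col = xc + (size_t)wi * H;
      for (; q < row_end; ++q, ++ho) {
        const int hi = ho * stride + oh;
        if (hi >= 0 && hi < H) pc[q - q0] = col[hi];
      }
    }
    (void)nq;
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector bias,
                            int stride, int pad, int dil) {
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_extent(H, kh, stride, pad, dil);
  const int Wo = out_extent(W, kw, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  const int K = kh * kw * Cin, npix = Ho * Wo;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y(npix * (size_t)Cout);
  arma::mat Y(y.begin(), npix, Cout, false, true);
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    // pointwise convolution: plain matrix product, no im2col
    const arma::mat X(const_cast<double*>(x.begin()), npix, Cin, false, true);
    Y = X * Wm;
  } else {
    const int block = std::max(1, std::min(npix, 1 << 22) / std::max(1, K));
    arma::mat P;
    for (int q0 = 0; q0 < npix; q0 += block) {
      const int q1 = std::min(npix, q0 + block);
      im2col_block(x.begin(), H, W, Cin, kh, kw, stride, pad, dil, Ho, q0, q1, P);
      Y.rows(q0, q1 - 1) = P * Wm;
    }
  }
  if (bias.size() == Cout) {
    for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector gout,
                   int stride, int pad, int dil, bool need_xgrad) {
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_extent(H, kh, stride, pad, dil);
  const int Wo = out_extent(W, kw, stride, pad, dil);
  const int K = kh * kw * Cin, npix = Ho * Wo;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const arma::mat G(const_cast<double*>(gout.begin()), npix, Cout, false, true);

  NumericVector gw(w.size()), gb(Cout), gx(need_xgrad ? x.size() : 0);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(G.col(co));

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    const arma::mat X(const_cast<double*>(x.begin()), npix, Cin, false, true);
    GW = X.t() * G;
    if (need_xgrad) {
      arma::mat GXm(gx.begin(), npix, Cin, false, true);
      GXm = G * Wm.t();
      gx.attr("dim") = xd;
    }
    gw.attr("dim") = wd;
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  const int block = std::max(1, std::min(npix, 1 << 22) / std::max(1, K));
  arma::mat P, GX;
  for (int q0 = 0; q0 < npix; q0 += block) {
    const int q1 = std::min(npix, q0 + block);
    im2col_block(x.begin(), H, W, Cin, kh, kw, stride, pad, dil, Ho, q0, q1, P);
    GW += P.t() * G.rows(q0, q1 - 1);
    if (need_xgrad) {
      GX = G.rows(q0, q1 - 1) * Wm.t();  // (block) x K
      for (int r = 0; r < K; ++r) {
        const int i = r % kh;
        const int j = (r / kh) % kw;
        const int ci = r / (kh * kw);
        double* xc = gx.begin() + (size_t)ci * H * W;
        const double* gc = GX.colptr(r);
        const int oh = dil * i - pad;
        const int ow = dil * j - pad;
        int q = q0;
        while (q < q1) {
          const int wo = q / Ho;
          const int wi = wo * stride + ow;
          int ho = q - wo * Ho;
          const int row_end = std::min(q1, (wo + 1) * Ho);
          if (wi < 0 || wi >= W) { q = row_end; continue; }
          double* col = xc + (size_t)wi * H;
          for (; q < row_end; ++q, ++ho) {
            const int hi = ho * stride + oh;
            if (hi >= 0 && hi < H) col[hi] += gc[q - q0];
          }
        }
      }
    }
  }
  if (need_xgrad) gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2, stride 2 (exact x2 upsampling, no overlap).
// w dims: (2, 2, Cin, Cout).
// [[Rcpp::export]]
NumericVector nn_convt2_fwd(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector bias) {
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int Cout = wd[3];
  const int npix = H * W;
  const arma::mat X(const_cast<double*>(x.begin()), npix, Cin, false, true);
  NumericVector y((size_t)4 * npix * Cout);
  const int Ho = 2 * H, Wo = 2 * W;
  for (int a = 0; a < 2; ++a) {
    for (int b = 0; b < 2; ++b) {
      arma::mat Wab(Cin, Cout);
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co)
          Wab(ci, co) = w[a + 2 * b + 4 * (ci + (size_t)Cin * co)];
      arma::mat Yab = X * Wab;  // npix x Cout
      for (int co = 0; co < Cout; ++co) {
        const double bb = bias.size() == Cout ? bias[co] : 0.0;
        double* yc = y.begin() + (size_t)co * Ho * Wo;
        for (int q = 0; q < npix; ++q) {
          const int hi = q % H, wi = q / H;
          yc[(2 * hi + a) + (size_t)(2 * wi + b) * Ho] = Yab(q, co) + bb;
        }
      }
    }
  }
  // bias added once per output pixel, but each output pixel is written exactly
  // once (one (a,b) pattern per parity), so the loop above is correct.
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return y;
}

// [[Rcpp::export]]
List nn_convt2_bwd(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector gout, bool need_xgrad) {
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int Cout = wd[3];
  const int npix = H * W, Ho = 2 * H, Wo = 2 * W;
  const arma::mat X(const_cast<double*>(x.begin()), npix, Cin, false, true);
  NumericVector gw(w.size()), gb(Cout), gx(need_xgrad ? x.size() : 0);
  arma::mat GX(need_xgrad ? gx.begin() : nullptr, need_xgrad ? npix : 0,
               need_xgrad ? Cin : 0, false, true);
  arma::mat Gab(npix, Cout);
  for (int a = 0; a < 2; ++a) {
    for (int b = 0; b < 2; ++b) {
      for (int co = 0; co < Cout; ++co) {
        const double* gc = gout.begin() + (size_t)co * Ho * Wo;
        for (int q = 0; q < npix; ++q) {
          const int hi = q % H, wi = q / H;
          Gab(q, co) = gc[(2 * hi + a) + (size_t)(2 * wi + b) * Ho];
        }
      }
      arma::mat GWab = X.t() * Gab;  // Cin x Cout
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co)
          gw[a + 2 * b + 4 * (ci + (size_t)Cin * co)] = GWab(ci, co);
      if (need_xgrad) {
        arma::mat Wab(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wab(ci, co) = w[a + 2 * b + 4 * (ci + (size_t)Cin * co)];
        GX += Gab * Wab.t();
      }
      for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gab.col(co));
    }
  }
  if (need_xgrad) gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 3x3 max pooling, stride 2, pad 1; argmax retained for the backward pass.
// [[Rcpp::export]]
List nn_maxpool3_fwd(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = out_extent(H, 3, 2, 1, 1), Wo = out_extent(W, 3, 2, 1, 1);
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector arg((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -HUGE_VAL; int bidx = -1;
        for (int dj = 0; dj < 3; ++dj) {
          const int wi = wo * 2 - 1 + dj;
          if (wi < 0 || wi >= W) continue;
          for (int di = 0; di < 3; ++di) {
            const int hi = ho * 2 - 1 + di;
            if (hi < 0 || hi >= H) continue;
            const double v = xc[hi + (size_t)wi * H];
            if (v > best) { best = v; bidx = hi + wi * H; }
          }
        }
        const size_t o = ho + (size_t)wo * Ho + (size_t)c * Ho * Wo;
        y[o] = best;
        arg[o] = bidx + c * H * W;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector nn_maxpool3_bwd(IntegerVector arg, NumericVector gout,
                              IntegerVector xd) {
  NumericVector gx((size_t)xd[0] * xd[1] * xd[2]);
  for (R_xlen_t q = 0; q < gout.size(); ++q) gx[arg[q]] += gout[q];
  gx.attr("dim") = xd;
  return gx;
}

// 2x2 average pooling, stride 2 (even input sides).
// [[Rcpp::export]]
NumericVector nn_avgpool2_fwd(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    double* yc = y.begin() + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yc[ho + (size_t)wo * Ho] = 0.25 *
          (xc[2 * ho + (size_t)(2 * wo) * H] + xc[2 * ho + 1 + (size_t)(2 * wo) * H] +
           xc[2 * ho + (size_t)(2 * wo + 1) * H] + xc[2 * ho + 1 + (size_t)(2 * wo + 1) * H]);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector nn_avgpool2_bwd(NumericVector gout, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx((size_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    const double* gc = gout.begin() + (size_t)c * Ho * Wo;
    double* xc = gx.begin() + (size_t)c * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * gc[ho + (size_t)wo * Ho];
        xc[2 * ho + (size_t)(2 * wo) * H] += g;
        xc[2 * ho + 1 + (size_t)(2 * wo) * H] += g;
        xc[2 * ho + (size_t)(2 * wo + 1) * H] += g;
        xc[2 * ho + 1 + (size_t)(2 * wo + 1) * H] += g;
      }
  }
  gx.attr("dim") = xd;
  return gx;
}

// Bilinear x2 upsampling with half-pixel centres (src = (out + 0.5)/2 - 0.5),
// edges clamped.
static inline void up2_coef(int io, int H, int& p0, int& p1, double& w1) {
  double src = (io + 0.5) / 2.0 - 0.5;
  if (src < 0) src = 0;
  if (src > H - 1) src = H - 1;
  p0 = (int)std::floor(src);
  p1 = std::min(p0 + 1, H - 1);
  w1 = src - p0;
}

// [[Rcpp::export]]
NumericVector nn_up2_bilinear_fwd(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C);
  std::vector<int> hp0(Ho), hp1(Ho), wp0(Wo), wp1(Wo);
  std::vector<double> hw(Ho), ww(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, hp0[i], hp1[i], hw[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, wp0[j], wp1[j], ww[j]);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    double* yc = y.begin() + (size_t)c * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double a = 1 - hw[i], b = hw[i], cL = 1 - ww[j], cR = ww[j];
        yc[i + (size_t)j * Ho] =
          cL * (a * xc[hp0[i] + (size_t)wp0[j] * H] + b * xc[hp1[i] + (size_t)wp0[j] * H]) +
          cR * (a * xc[hp0[i] + (size_t)wp1[j] * H] + b * xc[hp1[i] + (size_t)wp1[j] * H]);
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector nn_up2_bilinear_bwd(NumericVector gout, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((size_t)H * W * C);
  std::vector<int> hp0(Ho), hp1(Ho), wp0(Wo), wp1(Wo);
  std::vector<double> hw(Ho), ww(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, hp0[i], hp1[i], hw[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, wp0[j], wp1[j], ww[j]);
  for (int c = 0; c < C; ++c) {
    double* xc = gx.begin() + (size_t)c * H * W;
    const double* gc = gout.begin() + (size_t)c * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = gc[i + (size_t)j * Ho];
        const double a = 1 - hw[i], b = hw[i], cL = 1 - ww[j], cR = ww[j];
        xc[hp0[i] + (size_t)wp0[j] * H] += g * a * cL;
        xc[hp1[i] + (size_t)wp0[j] * H] += g * b * cL;
        xc[hp0[i] + (size_t)wp1[j] * H] += g * a * cR;
        xc[hp1[i] + (size_t)wp1[j] * H] += g * b * cR;
      }
  }
  gx.attr("dim") = xd;
  return gx;
}

// Generic resampling used by the augmentation pipeline (inference only, no
// gradients). xs/ys are 0-based fractional source coordinates per output
// pixel; boundary handling: reflect (mirror) or clamp.
static inline double reflect_coord(double t, int n) {
  if (n == 1) return 0;
  const double period = 2.0 * (n - 1);
  t -= period * std::floor(t / period);  // wrap into [0, period)
  return t > n - 1 ? period - t : t;
}

// [[Rcpp::export]]
NumericMatrix nn_sample_bilinear(NumericVector img, IntegerVector xd,
                                 NumericVector ys, NumericVector xs,
                                 bool reflect) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const R_xlen_t n = ys.size();
  NumericMatrix out(n, C);
  for (R_xlen_t q = 0; q < n; ++q) {
    double sy = ys[q], sx = xs[q];
    if (reflect) { sy = reflect_coord(sy, H); sx = reflect_coord(sx, W); }
    else {
      sy = std::min(std::max(sy, 0.0), (double)(H - 1));
      sx = std::min(std::max(sx, 0.0), (double)(W - 1));
    }
    const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
    const int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
    const double fy = sy - y0, fx = sx - x0;
    for (int c = 0; c < C; ++c) {
      const double* ic = img.begin() + (size_t)c * H * W;
      out(q, c) =
        (1 - fx) * ((1 - fy) * ic[y0 + (size_t)x0 * H] + fy * ic[y1 + (size_t)x0 * H]) +
        fx * ((1 - fy) * ic[y0 + (size_t)x1 * H] + fy * ic[y1 + (size_t)x1 * H]);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix nn_sample_nearest(NumericVector img, IntegerVector xd,
                                NumericVector ys, NumericVector xs,
                                bool reflect) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const R_xlen_t n = ys.size();
  NumericMatrix out(n, C);
  for (R_xlen_t q = 0; q < n; ++q) {
    double sy = ys[q], sx = xs[q];
    if (reflect) { sy = reflect_coord(sy, H); sx = reflect_coord(sx, W); }
    int iy = (int)std::lround(sy), ix = (int)std::lround(sx);
    iy = std::min(std::max(iy, 0), H - 1);
    ix = std::min(std::max(ix, 0), W - 1);
    for (int c = 0; c < C; ++c)
      out(q, c) = img[iy + (size_t)ix * H + (size_t)c * H * W];
  }
  return out;
}
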