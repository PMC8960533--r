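// Core dense tensor kernels for volumetric (rank-5) feature maps.
//
// Memory layout convention (column-major R arrays): an activation tensor has
// dim c(D, H, W, C, B) — spatial axes fastest, then channels, then batch.
// A convolution weight has dim c(k, k, k, Cin, Cout); flattened column-major
// it is the (k^3*Cin) x Cout matrix used in the GEMM formulation below.
//
// Convolutions use an im2col + GEMM scheme with the unrolled buffer stored
// transposed (output voxels x kernel taps): for the stride-1 "same"-padded
// case every kernel tap fills whole depth runs with contiguous copies,
// which keeps the unrolling cost at memcpy speed. The buffer is chunked
// over output voxels so it stays bounded even at full 64^3 resolution.
// 1^3 convolutions skip the unrolling and run as plain channel GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const arma::uword COL_CHUNK = 32768; // output voxels per im2col slab

struct ConvGeom {
  int D, H, W, Ci, B;     // input geometry
  int k, pad, stride;
  int Do, Ho, Wo, Co;     // output geometry
  arma::uword Nv_in, Nv_out, K;
  bool same;              // stride-1, size-preserving fast path
  ConvGeom(const IntegerVector& in_dims, int Co_, int k_, int pad_, int stride_) {
    D = in_dims[0]; H = in_dims[1]; W = in_dims[2];
    Ci = in_dims[3]; B = in_dims[4];
    k = k_; pad = pad_; stride = stride_; Co = Co_;
    Do = (D + 2 * pad - k) / stride + 1;
    Ho = (H + 2 * pad - k) / stride + 1;
    Wo = (W + 2 * pad - k) / stride + 1;
    Nv_in = (arma::uword)D * H * W;
    Nv_out = (arma::uword)Do * Ho * Wo;
    K = (arma::uword)k * k * k * Ci;
    same = stride == 1 && Do == D && Ho == H && Wo == W;
  }
  // chunk size aligned to whole depth runs, capped so the column buffer
  // stays around 16 MB regardless of K
  arma::uword chunk() const {
    arma::uword budget = (arma::uword)1 << 21; // doubles in the buffer
    arma::uword c = std::min<arma::uword>(COL_CHUNK, budget / std::max<arma::uword>(K, 1));
    c = (c / Do) * Do;
    if (c == 0) c = Do;
    return std::min<arma::uword>(c, Nv_out);
  }
};

// Fill the transposed im2col slab (nc x K) for output voxels [n0, n0+nc)
// of one batch item. Fast path: contiguous depth runs per kernel tap.
static void im2colT_slab(const double* xb, const ConvGeom& g,
                         arma::uword n0, arma::uword nc, arma::mat& colsT) {
  const int k = g.k;
  if (g.same) {
    for (int c = 0; c < g.Ci; ++c) {
      const double* xc = xb + (arma::uword)c * g.Nv_in;
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          for (int kd = 0; kd < k; ++kd) {
            arma::uword r = (arma::uword)k * k * k * c +
              (arma::uword)k * k * kw + (arma::uword)k * kh + kd;
            double* dst0 = colsT.colptr(r);
            int lo_clip = std::max(0, g.pad - kd);            // leading zeros
            int hi_valid = std::min(g.Do, g.D + g.pad - kd);  // first invalid od
            int run_len = hi_valid - lo_clip;
            for (arma::uword rs = 0; rs < nc; rs += g.Do) {
              arma::uword n = n0 + rs;
              int oh = (int)((n / g.Do) % g.Ho);
              int ow = (int)(n / ((arma::uword)g.Do * g.Ho));
              int ih = oh - g.pad + kh;
              int iw = ow - g.pad + kw;
              double* dst = dst0 + rs;
              if (ih < 0 || ih >= g.H || iw < 0 || iw >= g.W || run_len <= 0) {
                std::memset(dst, 0, sizeof(double) * g.Do);
                continue;
              }
              if (lo_clip > 0) std::memset(dst, 0, sizeof(double) * lo_clip);
              const double* src = xc + ((arma::uword)iw * g.H + ih) * g.D +
                (lo_clip - g.pad + kd);
              std::memcpy(dst + lo_clip, src, sizeof(double) * run_len);
              if (hi_valid < g.Do)
                std::memset(dst + hi_valid, 0,
                            sizeof(double) * (g.Do - hi_valid));
            }
          }
    }
    return;
  }
  // general (strided) path
  for (arma::uword i = 0; i < nc; ++i) {
    arma::uword n = n0 + i;
    int od = (int)(n % g.Do);
    int oh = (int)((n / g.Do) % g.Ho);
    int ow = (int)(n / ((arma::uword)g.Do * g.Ho));
    int id0 = od * g.stride - g.pad;
    int ih0 = oh * g.stride - g.pad;
    int iw0 = ow * g.stride - g.pad;
    for (int c = 0; c < g.Ci; ++c) {
      const double* xc = xb + (arma::uword)c * g.Nv_in;
      arma::uword r = (arma::uword)k * k * k * c;
      for (int kw = 0; kw < k; ++kw) {
        int iw = iw0 + kw;
        bool wok = iw >= 0 && iw < g.W;
        for (int kh = 0; kh < k; ++kh) {
          int ih = ih0 + kh;
          bool hok = wok && ih >= 0 && ih < g.H;
          const double* xrow = xc + ((arma::uword)iw * g.H + ih) * g.D;
          for (int kd = 0; kd < k; ++kd, ++r) {
            int id = id0 + kd;
            colsT(i, r) = (hok && id >= 0 && id < g.D) ? xrow[id] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the transposed slab back into the input gradient.
static void col2imT_slab(const arma::mat& colsT, const ConvGeom& g,
                         arma::uword n0, arma::uword nc, double* dxb) {
  const int k = g.k;
  if (g.same) {
    for (int c = 0; c < g.Ci; ++c) {
      double* xc = dxb + (arma::uword)c * g.Nv_in;
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          for (int kd = 0; kd < k; ++kd) {
            arma::uword r = (arma::uword)k * k * k * c +
              (arma::uword)k * k * kw + (arma::uword)k * kh + kd;
            const double* src0 = colsT.colptr(r);
            int lo_clip = std::max(0, g.pad - kd);
            int hi_valid = std::min(g.Do, g.D + g.pad - kd);
            int run_len = hi_valid - lo_clip;
            if (run_len <= 0) continue;
            for (arma::uword rs = 0; rs < nc; rs += g.Do) {
              arma::uword n = n0 + rs;
              int oh = (int)((n / g.Do) % g.Ho);
              int ow = (int)(n / ((arma::uword)g.Do * g.Ho));
              int ih = oh - g.pad + kh;
              int iw = ow - g.pad + kw;
              if (ih < 0 || ih >= g.H || iw < 0 || iw >= g.W) continue;
              const double* src = src0 + rs + lo_clip;
              double* dst = xc + ((arma::uword)iw * g.H + ih) * g.D +
                (lo_clip - g.pad + kd);
              for (int t = 0; t < run_len; ++t) dst[t] += src[t];
            }
          }
    }
    return;
  }
  for (arma::uword i = 0; i < nc; ++i) {
    arma::uword n = n0 + i;
    int od = (int)(n % g.Do);
    int oh = (int)((n / g.Do) % g.Ho);
    int ow = (int)(n / ((arma::uword)g.Do * g.Ho));
    int id0 = od * g.stride - g.pad;
    int ih0 = oh * g.stride - g.pad;
    int iw0 = ow * g.stride - g.pad;
    for (int c = 0; c < g.Ci; ++c) {
      double* xc = dxb + (arma::uword)c * g.Nv_in;
      arma::uword r = (arma::uword)k * k * k * c;
      for (int kw = 0; kw < k; ++kw) {
        int iw = iw0 + kw;
        bool wok = iw >= 0 && iw < g.W;
        for (int kh = 0; kh < k; ++kh) {
          int ih = ih0 + kh;
          bool hok = wok && ih >= 0 && ih < g.H;
          double* xrow = xc + ((arma::uword)iw * g.H + ih) * g.D;
          for (int kd = 0; kd < k; ++kd, ++r) {
            int id = id0 + kd;
            if (hok && id >= 0 && id < g.D) xrow[id] += colsT(i, r);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector in_dims,
                            NumericVector w, NumericVector bias,
                            int Co, int k, int pad, int stride) {
  ConvGeom g(in_dims, Co, k, pad, stride);
  const arma::mat W((double*)w.begin(), g.K, g.Co, false, true);
  NumericVector y((arma::uword)g.Nv_out * g.Co * g.B);
  if (k == 1 && stride == 1) { // pure channel GEMM
    for (int b = 0; b < g.B; ++b) {
      const arma::mat X((double*)x.begin() + (arma::uword)b * g.Nv_in * g.Ci,
                        g.Nv_in, g.Ci, false, true);
      arma::mat Y(y.begin() + (arma::uword)b * g.Nv_out * g.Co,
                  g.Nv_out, g.Co, false, true);
      Y = X * W;
      Y.each_row() += arma::rowvec((double*)bias.begin(), g.Co, false, true);
    }
    return y;
  }
  arma::uword chunk = g.chunk();
  arma::mat colsT(chunk, g.K);
  for (int b = 0; b < g.B; ++b) {
    const double* xb = x.begin() + (arma::uword)b * g.Nv_in * g.Ci;
    double* yb = y.begin() + (arma::uword)b * g.Nv_out * g.Co;
    for (arma::uword n0 = 0; n0 < g.Nv_out; n0 += chunk) {
      arma::uword nc = std::min<arma::uword>(chunk, g.Nv_out - n0);
      if (colsT.n_rows != nc) colsT.set_size(nc, g.K);
      im2colT_slab(xb, g, n0, nc, colsT);
      arma::mat out = colsT * W; // nc x Co
      for (int co = 0; co < g.Co; ++co) {
        double bsh = bias[co];
        const double* src = out.colptr(co);
        double* dst = yb + (arma::uword)co * g.Nv_out + n0;
        for (arma::uword i = 0; i < nc; ++i) dst[i] = src[i] + bsh;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3_bwd_data(NumericVector dy, IntegerVector in_dims,
                                 NumericVector w, int Co, int k, int pad,
                                 int stride) {
  ConvGeom g(in_dims, Co, k, pad, stride);
  const arma::mat W((double*)w.begin(), g.K, g.Co, false, true);
  NumericVector dx((arma::uword)g.Nv_in * g.Ci * g.B);
  if (k == 1 && stride == 1) {
    for (int b = 0; b < g.B; ++b) {
      const arma::mat dY((double*)dy.begin() +
                         (arma::uword)b * g.Nv_out * g.Co,
                         g.Nv_out, g.Co, false, true);
      arma::mat dX(dx.begin() + (arma::uword)b * g.Nv_in * g.Ci,
                   g.Nv_in, g.Ci, false, true);
      dX = dY * W.t();
    }
    return dx;
  }
  arma::uword chunk = g.chunk();
  for (int b = 0; b < g.B; ++b) {
    const double* dyb = dy.begin() + (arma::uword)b * g.Nv_out * g.Co;
    double* dxb = dx.begin() + (arma::uword)b * g.Nv_in * g.Ci;
    const arma::mat dyM((double*)dyb, g.Nv_out, g.Co, false, true);
    for (arma::uword n0 = 0; n0 < g.Nv_out; n0 += chunk) {
      arma::uword nc = std::min<arma::uword>(chunk, g.Nv_out - n0);
      arma::mat colsT = dyM.rows(n0, n0 + nc - 1) * W.t(); // nc x K
      col2imT_slab(colsT, g, n0, nc, dxb);
    }
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv3_bwd_filter(NumericVector x, NumericVector dy,
                          IntegerVector in_dims, int Co, int k, int pad,
                          int stride) {
  ConvGeom g(in_dims, Co, k, pad, stride);
  arma::mat dW(g.K, g.Co, arma::fill::zeros);
  arma::vec db(g.Co, arma::fill::zeros);
  if (k == 1 && stride == 1) {
    for (int b = 0; b < g.B; ++b) {
      const arma::mat X((double*)x.begin() + (arma::uword)b * g.Nv_in * g.Ci,
                        g.Nv_in, g.Ci, false, true);
      const arma::mat dY((double*)dy.begin() +
                         (arma::uword)b * g.Nv_out * g.Co,
                         g.Nv_out, g.Co, false, true);
      dW += X.t() * dY;
      db += arma::sum(dY, 0).t();
    }
    return List::create(Named("dw") = NumericVector(dW.begin(), dW.end()),
                        Named("db") = NumericVector(db.begin(), db.end()));
  }
  arma::uword chunk = g.chunk();
  arma::mat colsT(chunk, g.K);
  for (int b = 0; b < g.B; ++b) {
    const double* xb = x.begin() + (arma::uword)b * g.Nv_in * g.Ci;
    const double* dyb = dy.begin() + (arma::uword)b * g.Nv_out * g.Co;
    const arma::mat dyM((double*)dyb, g.Nv_out, g.Co, false, true);
    db += arma::sum(dyM, 0).t();
    for (arma::uword n0 = 0; n0 < g.Nv_out; n0 += chunk) {
      arma::uword nc = std::min<arma::uword>(chunk, g.Nv_out - n0);
      if (colsT.n_rows != nc) colsT.set_size(nc, g.K);
      im2colT_slab(xb, g, n0, nc, colsT);
      dW += colsT.t() * dyM.rows(n0, n0 + nc - 1);
    }
  }
  return List::create(Named("dw") = NumericVector(dW.begin(), dW.end()),
                      Named("db") = NumericVector(db.begin(), db.end()));
}

// 2^3 average pooling with stride 2 over the three spatial axes.
// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x, IntegerVector in_dims) {
  int D = in_dims[0], H = in_dims[1], W = in_dims[2];
  arma::uword CB = (arma::uword)in_dims[3] * in_dims[4];
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((arma::uword)Do * Ho * Wo * CB);
  for (arma::uword cb = 0; cb < CB; ++cb) {
    const double* xc = x.begin() + cb * (arma::uword)D * H * W;
    double* yc = y.begin() + cb * (arma::uword)Do * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          double s = 0.0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd)
                s += xc[(arma::uword)(2 * ow + dw) * H * D +
                        (arma::uword)(2 * oh + dh) * D + (2 * od + dd)];
          yc[(arma::uword)ow * Ho * Do + (arma::uword)oh * Do + od] = s / 8.0;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector dy, IntegerVector in_dims) {
  int D = in_dims[0], H = in_dims[1], W = in_dims[2];
  arma::uword CB = (arma::uword)in_dims[3] * in_dims[4];
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector dx((arma::uword)D * H * W * CB);
  for (arma::uword cb = 0; cb < CB; ++cb) {
    const double* dyc = dy.begin() + cb * (arma::uword)Do * Ho * Wo;
    double* dxc = dx.begin() + cb * (arma::uword)D * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          double gval =
              dyc[(arma::uword)ow * Ho * Do + (arma::uword)oh * Do + od] / 8.0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd)
                dxc[(arma::uword)(2 * ow + dw) * H * D +
                    (arma::uword)(2 * oh + dh) * D + (2 * od + dd)] += gval;
        }
  }
  return dx;
}

struct LinAxis {
  std::vector<int> i0, i1;
  std::vector<double> t;
};

// Half-voxel-centre (align_corners = FALSE) source coordinates, clamped at
// the boundaries: src = clamp((i + 0.5) * in/out - 0.5, 0, in - 1).
static LinAxis lin_axis(int in, int out) {
  LinAxis a;
  a.i0.resize(out); a.i1.resize(out); a.t.resize(out);
  double scale = (double)in / out;
  for (int i = 0; i < out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int lo = (int)std::floor(src);
    a.i0[i] = lo;
    a.i1[i] = std::min(lo + 1, in - 1);
    a.t[i] = src - lo;
  }
  return a;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3_fwd(NumericVector x, IntegerVector in_dims,
                                int Do, int Ho, int Wo) {
  int D = in_dims[0], H = in_dims[1], W = in_dims[2];
  arma::uword CB = (arma::uword)in_dims[3] * in_dims[4];
  LinAxis ad = lin_axis(D, Do), ah = lin_axis(H, Ho), aw = lin_axis(W, Wo);
  NumericVector y((arma::uword)Do * Ho * Wo * CB);
  for (arma::uword cb = 0; cb < CB; ++cb) {
    const double* xc = x.begin() + cb * (arma::uword)D * H * W;
    double* yc = y.begin() + cb * (arma::uword)Do * Ho * Wo;
    arma::uword n = 0;
    for (int ow = 0; ow < Wo; ++ow) {
      double tw = aw.t[ow];
      arma::uword w0 = (arma::uword)aw.i0[ow] * H * D;
      arma::uword w1 = (arma::uword)aw.i1[ow] * H * D;
      for (int oh = 0; oh < Ho; ++oh) {
        double th = ah.t[oh];
        arma::uword h0 = (arma::uword)ah.i0[oh] * D;
        arma::uword h1 = (arma::uword)ah.i1[oh] * D;
        for (int od = 0; od < Do; ++od, ++n) {
          double td = ad.t[od];
          int d0 = ad.i0[od], d1 = ad.i1[od];
          double c00 = xc[w0 + h0 + d0] * (1 - td) + xc[w0 + h0 + d1] * td;
          double c01 = xc[w0 + h1 + d0] * (1 - td) + xc[w0 + h1 + d1] * td;
          double c10 = xc[w1 + h0 + d0] * (1 - td) + xc[w1 + h0 + d1] * td;
          double c11 = xc[w1 + h1 + d0] * (1 - td) + xc[w1 + h1 + d1] * td;
          yc[n] = (c00 * (1 - th) + c01 * th) * (1 - tw) +
                  (c10 * (1 - th) + c11 * th) * tw;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3_bwd(NumericVector dy, IntegerVector in_dims,
                                int Do, int Ho, int Wo) {
  int D = in_dims[0], H = in_dims[1], W = in_dims[2];
  arma::uword CB = (arma::uword)in_dims[3] * in_dims[4];
  LinAxis ad = lin_axis(D, Do), ah = lin_axis(H, Ho), aw = lin_axis(W, Wo);
  NumericVector dx((arma::uword)D * H * W * CB);
  for (arma::uword cb = 0; cb < CB; ++cb) {
    const double* dyc = dy.begin() + cb * (arma::uword)Do * Ho * Wo;
    double* dxc = dx.begin() + cb * (arma::uword)D * H * W;
    arma::uword n = 0;
    for (int ow = 0; ow < Wo; ++ow) {
      double tw = aw.t[ow];
      arma::uword w0 = (arma::uword)aw.i0[ow] * H * D;
      arma::uword w1 = (arma::uword)aw.i1[ow] * H * D;
      for (int oh = 0; oh < Ho; ++oh) {
        double th = ah.t[oh];
        arma::uword h0 = (arma::uword)ah.i0[oh] * D;
        arma::uword h1 = (arma::uword)ah.i1[oh] * D;
        for (int od = 0; od < Do; ++od, ++n) {
          double td = ad.t[od];
          int d0 = ad.i0[od], d1 = ad.i1[od];
          double gval = dyc[n];
          dxc[w0 + h0 + d0] += gval * (1 - tw) * (1 - th) * (1 - td);
          dxc[w0 + h0 + d1] += gval * (1 - tw) * (1 - th) * td;
          dxc[w0 + h1 + d0] += gval * (1 - tw) * th * (1 - td);
          dxc[w0 + h1 + d1] += gval * (1 - tw) * th * td;
          dxc[w1 + h0 + d0] += gval * tw * (1 - th) * (1 - td);
          dxc[w1 + h0 + d1] += gval * tw * (1 - th) * td;
          dxc[w1 + h1 + d0] += gval * tw * th * (1 - td);
          dxc[w1 + h1 + d1] += gval * tw * th * td;
        }
      }
    }
  }
  return dx;
}
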