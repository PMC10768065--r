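// Low-level tensor kernels for the segmentation network.
//
// Feature maps are R arrays with dim = c(H, W, C, B) (column-major, so the
// flat index of element (h, w, c, b) is h + H*(w + W*(c + C*b)), all
// zero-based).  Convolution weights are arrays with dim = c(kh, kw, cpg,
// cout) where cpg = Cin / groups.  All convolutions in the architecture have
// stride 1; downsampling is done by max pooling and upsampling by bilinear
// interpolation, both provided here with their backward passes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::ivec dims_of(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  arma::ivec out(d.size());
  for (int i = 0; i < d.size(); ++i) out[i] = d[i];
  return out;
}

// Gather the im2col matrix (K x H*W) for image b, channel range
// [c0, c0 + cpg) of x, with zero padding `pad` and dilation `dil`.
static void im2col(const double* x, int H, int W, int C, int b,
                   int c0, int cpg, int kh, int kw, int pad, int dil,
                   arma::mat& col) {
  const int HW = H * W;
  col.zeros();
  for (int c = 0; c < cpg; ++c) {
    const double* xc = x + (size_t)HW * (c0 + c) + (size_t)HW * C * b;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const int oh = ki * dil - pad, ow = kj * dil - pad;
        for (int w = 0; w < W; ++w) {
          const int iw = w + ow;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
          const double* src = xc + (size_t)H * iw + oh;
          double* dst = col.colptr(0) + r; // col is K x HW, column = h + H*w
          for (int h = h0; h < h1; ++h) {
            dst[(size_t)col.n_rows * (h + (size_t)H * w)] = src[h];
          }
        }
      }
    }
  }
}

// Scatter-add of a gradient im2col matrix back into gx (col2im).
static void col2im(const arma::mat& col, double* gx, int H, int W, int C,
                   int b, int c0, int cpg, int kh, int kw, int pad, int dil) {
  const int HW = H * W;
  for (int c = 0; c < cpg; ++c) {
    double* xc = gx + (size_t)HW * (c0 + c) + (size_t)HW * C * b;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const int oh = ki * dil - pad, ow = kj * dil - pad;
        for (int w = 0; w < W; ++w) {
          const int iw = w + ow;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
          double* dst = xc + (size_t)H * iw + oh;
          const double* src = col.colptr(0) + r;
          for (int h = h0; h < h1; ++h) {
            dst[h] += src[(size_t)col.n_rows * (h + (size_t)H * w)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        Nullable<NumericVector> bias,
                        int pad, int dil, int groups) {
  arma::ivec xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], cpg = wd[2], cout = wd[3];
  if (C != cpg * groups) stop("conv2d: input channels do not match weights");
  if (cout % groups != 0) stop("conv2d: cout not divisible by groups");
  const int copg = cout / groups, HW = H * W, K = kh * kw * cpg;

  NumericVector y((size_t)HW * cout * B);
  y.attr("dim") = IntegerVector::create(H, W, cout, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* bp = bias.isNotNull() ? NumericVector(bias).begin() : nullptr;

  arma::mat col(K, HW);
  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, C, b, g * cpg, cpg, kh, kw, pad, dil, col);
      // weight block for this group's outputs is contiguous: K x copg
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)K * copg * g,
                   K, copg, false, true);
      arma::mat out = Wm.t() * col; // copg x HW
      for (int o = 0; o < copg; ++o) {
        const int oc = g * copg + o;
        double* dst = yp + (size_t)HW * oc + (size_t)HW * cout * b;
        const double add = bp ? bp[oc] : 0.0;
        for (int i = 0; i < HW; ++i) dst[i] = out(o, i) + add;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               bool has_bias, int pad, int dil, int groups) {
  arma::ivec xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], cpg = wd[2], cout = wd[3];
  const int copg = cout / groups, HW = H * W, K = kh * kw * cpg;

  NumericVector gx((size_t)HW * C * B), gw(w.size());
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(has_bias ? cout : 0);

  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();

  arma::mat col(K, HW), Gy(copg, HW);
  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, C, b, g * cpg, cpg, kh, kw, pad, dil, col);
      for (int o = 0; o < copg; ++o) {
        const int oc = g * copg + o;
        const double* src = gyp + (size_t)HW * oc + (size_t)HW * cout * b;
        double acc = 0.0;
        for (int i = 0; i < HW; ++i) { Gy(o, i) = src[i]; acc += src[i]; }
        if (has_bias) gb[oc] += acc;
      }
      arma::mat gWm(gw.begin() + (size_t)K * copg * g, K, copg, false, true);
      gWm += col * Gy.t();
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)K * copg * g,
                   K, copg, false, true);
      arma::mat gcol = Wm * Gy; // K x HW
      col2im(gcol, gxp, H, W, C, b, g * cpg, cpg, kh, kw, pad, dil);
    }
  }
  if (has_bias) return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// 2x2 max pooling with stride 2.  Returns the pooled map and the flat
// (1-based) argmax index into x for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  arma::ivec xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int cb = 0; cb < C * B; ++cb) {
    const size_t base = (size_t)H * W * cb;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h, ++o) {
        size_t i00 = base + 2 * h + (size_t)H * (2 * w);
        size_t best = i00;
        double v = xp[i00];
        const size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
        for (int k = 0; k < 3; ++k)
          if (xp[cand[k]] > v) { v = xp[cand[k]]; best = cand[k]; }
        yp[o] = v;
        ip[o] = (int)(best + 1);
      }
    }
  }
  idx.attr("dim") = y.attr("dim");
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector gy, IntegerVector idx,
                          IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double* gp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) gp[idx[i] - 1] += gy[i];
  return gx;
}

// Bilinear x2 upsampling with half-pixel centres (align_corners = FALSE).
static void bilin_weights(int Ho, int H, std::vector<int>& i0,
                          std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(Ho); i1.resize(Ho); a.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    double f = std::floor(s);
    int lo = (int)f;
    double t = s - f;
    i0[i] = std::min(std::max(lo, 0), H - 1);
    i1[i] = std::min(std::max(lo + 1, 0), H - 1);
    a[i] = t;
  }
}

// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x) {
  arma::ivec xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1; std::vector<double> th, tw;
  bilin_weights(Ho, H, h0, h1, th);
  bilin_weights(Wo, W, w0, w1, tw);
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const double* xs = xp + (size_t)H * W * cb;
    double* ys = yp + (size_t)Ho * Wo * cb;
    for (int w = 0; w < Wo; ++w) {
      const double* cl = xs + (size_t)H * w0[w];
      const double* cr = xs + (size_t)H * w1[w];
      for (int h = 0; h < Ho; ++h) {
        double top = cl[h0[h]] * (1 - tw[w]) + cr[h0[h]] * tw[w];
        double bot = cl[h1[h]] * (1 - tw[w]) + cr[h1[h]] * tw[w];
        ys[h + (size_t)Ho * w] = top * (1 - th[h]) + bot * th[h];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector gy) {
  arma::ivec yd = dims_of(gy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  std::vector<int> h0, h1, w0, w1; std::vector<double> th, tw;
  bilin_weights(Ho, H, h0, h1, th);
  bilin_weights(Wo, W, w0, w1, tw);
  NumericVector gx((size_t)H * W * C * B);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    double* xs = xp + (size_t)H * W * cb;
    const double* ys = gp + (size_t)Ho * Wo * cb;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const double g = ys[h + (size_t)Ho * w];
        xs[h0[h] + (size_t)H * w0[w]] += g * (1 - th[h]) * (1 - tw[w]);
        xs[h1[h] + (size_t)H * w0[w]] += g * th[h] * (1 - tw[w]);
        xs[h0[h] + (size_t)H * w1[w]] += g * (1 - th[h]) * tw[w];
        xs[h1[h] + (size_t)H * w1[w]] += g * th[h] * tw[w];
      }
    }
  }
  return gx;
}

// Per-class one-vs-rest confusion counts for two integer label grids with
// values in [0, num_classes).  Returns a num_classes x 4 matrix of
// (tp, fp, fn, tn) as doubles (counts can exceed .Machine$integer.max
// when aggregated upstream; here they fit but we stay consistent).
// [[Rcpp::export(name = ".confusion_fw")]]
NumericMatrix confusion_fw(IntegerVector pred, IntegerVector truth,
                           int num_classes) {
  if (pred.size() != truth.size()) stop("confusion: shape mismatch");
  std::vector<double> joint((size_t)num_classes * num_classes, 0.0);
  for (R_xlen_t i = 0; i < pred.size(); ++i) {
    const int p = pred[i], t = truth[i];
    if (p < 0 || p >= num_classes || t < 0 || t >= num_classes)
      stop("confusion: label out of range [0, num_classes)");
    joint[p + (size_t)num_classes * t] += 1.0;
  }
  const double n = (double)pred.size();
  NumericMatrix out(num_classes, 4);
  colnames(out) = CharacterVector::create("tp", "fp", "fn", "tn");
  for (int c = 0; c < num_classes; ++c) {
    double tp = joint[c + (size_t)num_classes * c];
    double predc = 0, truec = 0;
    for (int k = 0; k < num_classes; ++k) {
      predc += joint[c + (size_t)num_classes * k];
      truec += joint[k + (size_t)num_classes * c];
    }
    out(c, 0) = tp;
    out(c, 1) = predc - tp;
    out(c, 2) = truec - tp;
    out(c, 3) = n - predc - truec + tp;
  }
  return out;
}
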