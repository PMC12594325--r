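// Convolution and texture primitives for the classification pipeline.
// Array layout throughout: feature maps are R arrays with dim (C, H, W, N);
// convolution weights have dim (kh, kw, Cin/groups, Cout). conv2d_* compute
// cross-correlation (deep-learning convention, no kernel flip).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Build the im2col matrix for one image and one channel group.
// x: pointer to image n, channels [c0, c0+Cg). Rows of `col` are indexed
// q = ki + kh*kj + kh*kw*ci (matching the weight flattening), columns are
// output pixels ho + Ho*wo.
static void im2col(const double* x, int C, int H, int W,
                   int c0, int Cg, int kh, int kw,
                   int stride, int pad, int pad_mode,
                   int Ho, int Wo, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int outpix = ho + Ho * wo;
      for (int ci = 0; ci < Cg; ++ci) {
        const int c = c0 + ci;
        for (int kj = 0; kj < kw; ++kj) {
          int wsrc = wo * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int hsrc = ho * stride - pad + ki;
            const int q = ki + kh * (kj + kw * ci);
            double v;
            if (pad_mode == 1) { // replicate
              int hc = clampi(hsrc, 0, H - 1);
              int wc = clampi(wsrc, 0, W - 1);
              v = x[c + C * (hc + H * wc)];
            } else {             // zero padding
              if (hsrc < 0 || hsrc >= H || wsrc < 0 || wsrc >= W) v = 0.0;
              else v = x[c + C * (hsrc + H * wsrc)];
            }
            col(q, outpix) = v;
          }
        }
      }
    }
  }
}

// Scatter-add of a column-gradient matrix back onto the input image.
static void col2im(double* dx, int C, int H, int W,
                   int c0, int Cg, int kh, int kw,
                   int stride, int pad, int pad_mode,
                   int Ho, int Wo, const arma::mat& colg) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int outpix = ho + Ho * wo;
      for (int ci = 0; ci < Cg; ++ci) {
        const int c = c0 + ci;
        for (int kj = 0; kj < kw; ++kj) {
          int wsrc = wo * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int hsrc = ho * stride - pad + ki;
            const int q = ki + kh * (kj + kw * ci);
            if (pad_mode == 1) {
              int hc = clampi(hsrc, 0, H - 1);
              int wc = clampi(wsrc, 0, W - 1);
              dx[c + C * (hc + H * wc)] += colg(q, outpix);
            } else {
              if (hsrc < 0 || hsrc >= H || wsrc < 0 || wsrc >= W) continue;
              dx[c + C * (hsrc + H * wsrc)] += colg(q, outpix);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int pad, int pad_mode, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("conv2d: input channels (%d) != groups (%d) * kernel channels (%d)", C, groups, Cg);
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  const int Cog = Cout / groups;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty (input %dx%d, kernel %dx%d)", H, W, kh, kw);

  NumericVector out(static_cast<R_xlen_t>(Cout) * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  const bool has_bias = bias.size() > 0;

  arma::mat col(Cg * kh * kw, Ho * Wo);
  for (int g = 0; g < groups; ++g) {
    // weight slice for group g: Cout rows co in [g*Cog, (g+1)*Cog)
    arma::mat Wm(Cog, Cg * kh * kw);
    for (int co = 0; co < Cog; ++co)
      for (int q = 0; q < Cg * kh * kw; ++q)
        Wm(co, q) = w[q + Cg * kh * kw * (g * Cog + co)];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
      im2col(xp, C, H, W, g * Cg, Cg, kh, kw, stride, pad, pad_mode, Ho, Wo, col);
      arma::mat y = Wm * col; // (Cog x Ho*Wo)
      double* op = out.begin() + static_cast<R_xlen_t>(n) * Cout * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p)
        for (int co = 0; co < Cog; ++co) {
          double v = y(co, p);
          if (has_bias) v += bias[g * Cog + co];
          op[(g * Cog + co) + Cout * p] = v;
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int pad_mode, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int Ho = yd[1], Wo = yd[2];
  const int Cog = Cout / groups;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat col(Cg * kh * kw, Ho * Wo);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Cog, Cg * kh * kw);
    for (int co = 0; co < Cog; ++co)
      for (int q = 0; q < Cg * kh * kw; ++q)
        Wm(co, q) = w[q + Cg * kh * kw * (g * Cog + co)];
    arma::mat dWm(Cog, Cg * kh * kw, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + static_cast<R_xlen_t>(n) * C * H * W;
      im2col(xp, C, H, W, g * Cg, Cg, kh, kw, stride, pad, pad_mode, Ho, Wo, col);
      arma::mat dyg(Cog, Ho * Wo);
      const double* dyp = dy.begin() + static_cast<R_xlen_t>(n) * Cout * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p)
        for (int co = 0; co < Cog; ++co) {
          double v = dyp[(g * Cog + co) + Cout * p];
          dyg(co, p) = v;
          db[g * Cog + co] += v;
        }
      dWm += dyg * col.t();
      arma::mat colg = Wm.t() * dyg;
      double* dxp = dx.begin() + static_cast<R_xlen_t>(n) * C * H * W;
      col2im(dxp, C, H, W, g * Cg, Cg, kh, kw, stride, pad, pad_mode, Ho, Wo, colg);
    }
    for (int co = 0; co < Cog; ++co)
      for (int q = 0; q < Cg * kh * kw; ++q)
        dw[q + Cg * kh * kw * (g * Cog + co)] = dWm(co, q);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear sample with replicate (clamped) borders; (r, c) in 0-based pixels.
static inline double sample_bilinear(const NumericMatrix& img, double r, double c) {
  const int H = img.nrow(), W = img.ncol();
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double tr = r - r0, tc = c - c0;
  int r0c = clampi(r0, 0, H - 1), r1c = clampi(r0 + 1, 0, H - 1);
  int c0c = clampi(c0, 0, W - 1), c1c = clampi(c0 + 1, 0, W - 1);
  // reduce when clamping collapses sample points or the neighbourhood is
  // constant, so exact ties are not disturbed by floating-point rounding
  if (img(r0c, c0c) == img(r0c, c1c) && img(r0c, c0c) == img(r1c, c0c) &&
      img(r0c, c0c) == img(r1c, c1c)) return img(r0c, c0c);
  if (r0c == r1c && c0c == c1c) return img(r0c, c0c);
  if (r0c == r1c)
    return (1 - tc) * img(r0c, c0c) + tc * img(r0c, c1c);
  if (c0c == c1c)
    return (1 - tr) * img(r0c, c0c) + tr * img(r1c, c0c);
  return (1 - tr) * (1 - tc) * img(r0c, c0c) + (1 - tr) * tc * img(r0c, c1c) +
         tr * (1 - tc) * img(r1c, c0c) + tr * tc * img(r1c, c1c);
}

// Local binary pattern codes on a circular neighborhood. Neighbor k = 0 sits
// at angle 0 (east), angles increase counter-clockwise; samples off the pixel
// grid use bilinear interpolation, borders replicate. Ties (neighbor equal to
// center) score 1.
// [[Rcpp::export]]
NumericMatrix lbp_encode_cpp(NumericMatrix img, int P, double R) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  std::vector<double> dr(P), dc(P);
  for (int k = 0; k < P; ++k) {
    double theta = 2.0 * M_PI * k / P;
    dc[k] = R * std::cos(theta);
    dr[k] = -R * std::sin(theta); // row index grows downward
    // snap near-integer offsets so axis-aligned neighbours are sampled
    // exactly (cos(pi/2) is ~6e-17, not 0, in floating point)
    if (std::fabs(dc[k] - std::round(dc[k])) < 1e-9) dc[k] = std::round(dc[k]);
    if (std::fabs(dr[k] - std::round(dr[k])) < 1e-9) dr[k] = std::round(dr[k]);
  }
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double center = img(r, c);
      double code = 0.0, bit = 1.0;
      for (int k = 0; k < P; ++k) {
        double v = sample_bilinear(img, r + dr[k], c + dc[k]);
        if (v >= center) code += bit;
        bit *= 2.0;
      }
      out(r, c) = code;
    }
  }
  return out;
}
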