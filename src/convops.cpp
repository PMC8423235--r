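#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim = (H, W, C, N), column-major, so index
// (h, w, c, n) lives at h + H*(w + W*(c + C*n)).  Weights for a 2-D
// convolution are (kh, kw, Cin, Cout).  All convolutions are stride 1 with
// explicit zero padding; dilated taps index x at offsets scaled by `dil`.
// Loops are arranged so the innermost runs down contiguous columns (the H
// axis) of both operands.

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xd,
                        NumericVector wt, IntegerVector wd,
                        NumericVector bias, int pad, int dil) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], O = wd[3];
  const int Ho = H + 2 * pad - dil * (kh - 1);
  const int Wo = W + 2 * pad - dil * (kw - 1);
  NumericVector y((R_xlen_t)Ho * Wo * O * N);
  const double *px = x.begin(), *pw = wt.begin();
  double *py = y.begin();
  const bool has_b = bias.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < O; ++o) {
      double *yp = py + (R_xlen_t)Ho * Wo * (o + (R_xlen_t)O * n);
      if (has_b) {
        const double b0 = bias[o];
        for (int t = 0; t < Ho * Wo; ++t) yp[t] = b0;
      }
      for (int c = 0; c < C; ++c) {
        const double *xp = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
        const double *wp = pw + (R_xlen_t)kh * kw * (c + (R_xlen_t)C * o);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const double w0 = wp[i + kh * j];
            if (w0 == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo - pad + dil * j;
              if (wi < 0 || wi >= W) continue;
              const int ho_lo = std::max(0, pad - dil * i);
              const int ho_hi = std::min(Ho, H + pad - dil * i);
              const double *xcol = xp + (R_xlen_t)H * wi - pad + dil * i;
              double *ycol = yp + (R_xlen_t)Ho * wo;
              for (int ho = ho_lo; ho < ho_hi; ++ho)
                ycol[ho] += w0 * xcol[ho];
            }
          }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, IntegerVector xd,
               NumericVector wt, IntegerVector wd,
               NumericVector gy, int pad, int dil, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], O = wd[3];
  const int Ho = H + 2 * pad - dil * (kh - 1);
  const int Wo = W + 2 * pad - dil * (kw - 1);
  NumericVector gx(x.size()), gw(wt.size()), gb(has_bias ? O : 0);
  const double *px = x.begin(), *pw = wt.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < O; ++o) {
      const double *gp = pg + (R_xlen_t)Ho * Wo * (o + (R_xlen_t)O * n);
      if (has_bias) {
        double acc = 0;
        for (int t = 0; t < Ho * Wo; ++t) acc += gp[t];
        gb[o] += acc;
      }
      for (int c = 0; c < C; ++c) {
        const double *xp = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
        double *gxp = pgx + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
        const double *wp = pw + (R_xlen_t)kh * kw * (c + (R_xlen_t)C * o);
        double *gwp = pgw + (R_xlen_t)kh * kw * (c + (R_xlen_t)C * o);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const double w0 = wp[i + kh * j];
            double wacc = 0;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo - pad + dil * j;
              if (wi < 0 || wi >= W) continue;
              const int ho_lo = std::max(0, pad - dil * i);
              const int ho_hi = std::min(Ho, H + pad - dil * i);
              const double *xcol = xp + (R_xlen_t)H * wi - pad + dil * i;
              double *gxcol = gxp + (R_xlen_t)H * wi - pad + dil * i;
              const double *gcol = gp + (R_xlen_t)Ho * wo;
              for (int ho = ho_lo; ho < ho_hi; ++ho) {
                const double g = gcol[ho];
                gxcol[ho] += w0 * g;
                wacc += xcol[ho] * g;
              }
            }
            gwp[i + kh * j] += wacc;
          }
      }
    }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 3, stride 2, padding 1, output padding 1:
// output is exactly 2H x 2W.  Output position oh receives input row ih and
// tap i where oh = 2*ih - 1 + i.
// [[Rcpp::export]]
NumericVector tconv2d_fw(NumericVector x, IntegerVector xd,
                         NumericVector wt, IntegerVector wd,
                         NumericVector bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], O = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * O * N);
  const double *px = x.begin(), *pw = wt.begin();
  double *py = y.begin();
  const bool has_b = bias.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < O; ++o) {
      double *yp = py + (R_xlen_t)Ho * Wo * (o + (R_xlen_t)O * n);
      if (has_b) {
        const double b0 = bias[o];
        for (int t = 0; t < Ho * Wo; ++t) yp[t] = b0;
      }
      for (int c = 0; c < C; ++c) {
        const double *xp = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
        const double *wp = pw + (R_xlen_t)kh * kw * (c + (R_xlen_t)C * o);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const double w0 = wp[i + kh * j];
            if (w0 == 0.0) continue;
            const int hi0 = (i == 0) ? 1 : 0;   // keep oh = 2hi-1+i in range
            const int wi0 = (j == 0) ? 1 : 0;
            const int hi1 = (i == 2) ? H : H;   // oh <= 2H-1 always holds
            for (int wi = wi0; wi < W; ++wi) {
              const int wo = 2 * wi - 1 + j;
              if (wo >= Wo) continue;
              const double *xcol = xp + (R_xlen_t)H * wi;
              double *ycol = yp + (R_xlen_t)Ho * wo - 1 + i;
              for (int hi = hi0; hi < hi1; ++hi) {
                const int oh = 2 * hi;
                if (oh - 1 + i >= Ho) break;
                ycol[oh] += w0 * xcol[hi];
              }
            }
          }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  return y;
}

// [[Rcpp::export]]
List tconv2d_bw(NumericVector x, IntegerVector xd,
                NumericVector wt, IntegerVector wd,
                NumericVector gy, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], O = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size()), gw(wt.size()), gb(has_bias ? O : 0);
  const double *px = x.begin(), *pw = wt.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < O; ++o) {
      const double *gp = pg + (R_xlen_t)Ho * Wo * (o + (R_xlen_t)O * n);
      if (has_bias) {
        double acc = 0;
        for (int t = 0; t < Ho * Wo; ++t) acc += gp[t];
        gb[o] += acc;
      }
      for (int c = 0; c < C; ++c) {
        const double *xp = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
        double *gxp = pgx + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
        const double *wp = pw + (R_xlen_t)kh * kw * (c + (R_xlen_t)C * o);
        double *gwp = pgw + (R_xlen_t)kh * kw * (c + (R_xlen_t)C * o);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const double w0 = wp[i + kh * j];
            double wacc = 0;
            const int hi0 = (i == 0) ? 1 : 0;
            const int wi0 = (j == 0) ? 1 : 0;
            for (int wi = wi0; wi < W; ++wi) {
              const int wo = 2 * wi - 1 + j;
              if (wo >= Wo) continue;
              const double *xcol = xp + (R_xlen_t)H * wi;
              double *gxcol = gxp + (R_xlen_t)H * wi;
              const double *gcol = gp + (R_xlen_t)Ho * wo - 1 + i;
              for (int hi = hi0; hi < H; ++hi) {
                const int oh = 2 * hi;
                if (oh - 1 + i >= Ho) break;
                const double g = gcol[oh];
                gxcol[hi] += w0 * g;
                wacc += xcol[hi] * g;
              }
            }
            gwp[i + kh * j] += wacc;
          }
      }
    }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the flat index of the
// winning input cell so the backward pass can route gradients exactly.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector arg(y.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int bi = -1;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const int xi = idx4(2 * ho + dh, 2 * wo + dw, c, n, H, W, C);
              if (x[xi] > best) { best = x[xi]; bi = xi; }
            }
          const int yi = idx4(ho, wo, c, n, Ho, Wo, C);
          y[yi] = best; arg[yi] = bi;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector gy, IntegerVector arg, IntegerVector xd) {
  NumericVector gx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[arg[i]] += gy[i];
  gx.attr("dim") = xd;
  return gx;
}
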