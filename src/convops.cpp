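// Convolution / pooling / resampling kernels for the segmentation network.
// All arrays are R column-major numeric arrays in (batch B, channel C, height H,
// width W) order: element (b,c,h,w) lives at b + B*(c + C*(h + H*w)).
// Convolution weights are (CO, Cg, KH, KW) with Cg = C/groups.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int in, int pad, int k, int stride) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix for one (batch, group): rows ci + Cg*(kh + KH*kw),
// columns ho + HO*wo. Out-of-image taps are zero (same zero padding).
static void im2col_fill(const double* x, int B, int C, int H, int W,
                        int b, int g, int Cg, int KH, int KW,
                        int stride, int ph, int pw, int HO, int WO,
                        arma::mat& col) {
  for (int wo = 0; wo < WO; ++wo) {
    for (int ho = 0; ho < HO; ++ho) {
      const int j = ho + HO * wo;
      for (int kw = 0; kw < KW; ++kw) {
        const int wi = wo * stride - pw + kw;
        for (int kh = 0; kh < KH; ++kh) {
          const int hi = ho * stride - ph + kh;
          const bool inb = hi >= 0 && hi < H && wi >= 0 && wi < W;
          for (int ci = 0; ci < Cg; ++ci) {
            const int c = g * Cg + ci;
            col(ci + Cg * (kh + KH * kw), j) =
              inb ? x[b + (std::size_t)B * (c + (std::size_t)C * (hi + (std::size_t)H * wi))] : 0.0;
          }
        }
      }
    }
  }
}

static arma::mat weight_mat(const double* w, int CO, int Cg, int KH, int KW,
                            int g, int COg) {
  arma::mat Wg(COg, Cg * KH * KW);
  for (int og = 0; og < COg; ++og) {
    const int o = g * COg + og;
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh)
        for (int ci = 0; ci < Cg; ++ci)
          Wg(og, ci + Cg * (kh + KH * kw)) =
            w[o + (std::size_t)CO * (ci + (std::size_t)Cg * (kh + (std::size_t)KH * kw))];
  }
  return Wg;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector bias,
                            int stride, int ph, int pw, int groups) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int CO = wd[0], Cg = wd[1], KH = wd[2], KW = wd[3];
  if (C % groups != 0 || CO % groups != 0 || Cg != C / groups)
    stop("conv2d: inconsistent channel/group configuration");
  const int COg = CO / groups;
  const int HO = out_extent(H, ph, KH, stride), WO = out_extent(W, pw, KW, stride);
  if (HO < 1 || WO < 1) stop("conv2d: output extent < 1");

  NumericVector out((std::size_t)B * CO * HO * WO);
  out.attr("dim") = IntegerVector::create(B, CO, HO, WO);
  double* po = REAL(out);
  const double* px = REAL(x);

  arma::mat col(Cg * KH * KW, HO * WO);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wg = weight_mat(REAL(w), CO, Cg, KH, KW, g, COg);
    for (int b = 0; b < B; ++b) {
      im2col_fill(px, B, C, H, W, b, g, Cg, KH, KW, stride, ph, pw, HO, WO, col);
      arma::mat og = Wg * col;  // COg x HO*WO
      for (int j = 0; j < HO * WO; ++j) {
        const int ho = j % HO, wo = j / HO;
        for (int oc = 0; oc < COg; ++oc) {
          const int o = g * COg + oc;
          po[b + (std::size_t)B * (o + (std::size_t)CO * (ho + (std::size_t)HO * wo))] =
            og(oc, j) + bias[o];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector gout,
                   int stride, int ph, int pw, int groups) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int CO = wd[0], Cg = wd[1], KH = wd[2], KW = wd[3];
  const int COg = CO / groups;
  const int HO = out_extent(H, ph, KH, stride), WO = out_extent(W, pw, KW, stride);

  NumericVector gx((std::size_t)B * C * H * W);
  gx.attr("dim") = IntegerVector::create(B, C, H, W);
  NumericVector gw((std::size_t)CO * Cg * KH * KW);
  gw.attr("dim") = IntegerVector::create(CO, Cg, KH, KW);
  NumericVector gb(CO);

  const double* px = REAL(x);
  const double* pg = REAL(gout);
  double* pgx = REAL(gx);
  double* pgw = REAL(gw);

  arma::mat col(Cg * KH * KW, HO * WO);
  arma::mat G(COg, HO * WO);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wg = weight_mat(REAL(w), CO, Cg, KH, KW, g, COg);
    arma::mat GW(COg, Cg * KH * KW, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int j = 0; j < HO * WO; ++j) {
        const int ho = j % HO, wo = j / HO;
        for (int oc = 0; oc < COg; ++oc) {
          const int o = g * COg + oc;
          const double v =
            pg[b + (std::size_t)B * (o + (std::size_t)CO * (ho + (std::size_t)HO * wo))];
          G(oc, j) = v;
          gb[o] += v;
        }
      }
      im2col_fill(px, B, C, H, W, b, g, Cg, KH, KW, stride, ph, pw, HO, WO, col);
      GW += G * col.t();
      arma::mat colg = Wg.t() * G;  // (Cg*KH*KW) x HO*WO, scatter-add (col2im)
      for (int wo = 0; wo < WO; ++wo) {
        for (int ho = 0; ho < HO; ++ho) {
          const int j = ho + HO * wo;
          for (int kw = 0; kw < KW; ++kw) {
            const int wi = wo * stride - pw + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < KH; ++kh) {
              const int hi = ho * stride - ph + kh;
              if (hi < 0 || hi >= H) continue;
              for (int ci = 0; ci < Cg; ++ci) {
                const int c = g * Cg + ci;
                pgx[b + (std::size_t)B * (c + (std::size_t)C * (hi + (std::size_t)H * wi))] +=
                  colg(ci + Cg * (kh + KH * kw), j);
              }
            }
          }
        }
      }
    }
    for (int oc = 0; oc < COg; ++oc) {
      const int o = g * COg + oc;
      for (int kw = 0; kw < KW; ++kw)
        for (int kh = 0; kh < KH; ++kh)
          for (int ci = 0; ci < Cg; ++ci)
            pgw[o + (std::size_t)CO * (ci + (std::size_t)Cg * (kh + (std::size_t)KH * kw))] =
              GW(oc, ci + Cg * (kh + KH * kw));
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling with argmax bookkeeping (1-based linear index into x) for backward.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xd, int k, int stride, int pad) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int HO = out_extent(H, pad, k, stride), WO = out_extent(W, pad, k, stride);
  NumericVector out((std::size_t)B * C * HO * WO);
  out.attr("dim") = IntegerVector::create(B, C, HO, WO);
  IntegerVector arg((std::size_t)B * C * HO * WO);
  const double* px = REAL(x);
  double* po = REAL(out);
  std::size_t n = 0;
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho)
      for (int c = 0; c < C; ++c)
        for (int b = 0; b < B; ++b) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const std::size_t ix =
                b + (std::size_t)B * (c + (std::size_t)C * (hi + (std::size_t)H * wi));
              if (px[ix] > best) { best = px[ix]; bi = ix; }
            }
          }
          const std::size_t io =
            b + (std::size_t)B * (c + (std::size_t)C * (ho + (std::size_t)HO * wo));
          po[io] = best;
          arg[io] = (int)(bi + 1);
          ++n;
        }
  (void)n;
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gout, IntegerVector argmax, IntegerVector xd) {
  NumericVector gx((std::size_t)xd[0] * xd[1] * xd[2] * xd[3]);
  gx.attr("dim") = xd;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i] - 1] += gout[i];
  return gx;
}

// Factor-2 bilinear upsampling, half-pixel-centre convention (edge-clamped).
static void up2_weights(int HO, int H, std::vector<int>& i0, std::vector<int>& i1,
                        std::vector<double>& w1) {
  i0.resize(HO); i1.resize(HO); w1.resize(HO);
  for (int o = 0; o < HO; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int f = (int)std::floor(s);
    if (f > H - 2) f = H - 2;
    if (f < 0) f = 0;
    i0[o] = f;
    i1[o] = (H > 1) ? f + 1 : f;
    w1[o] = (H > 1) ? s - f : 0.0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_fw(NumericVector x, IntegerVector xd) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int HO = 2 * H, WO = 2 * W;
  NumericVector out((std::size_t)B * C * HO * WO);
  out.attr("dim") = IntegerVector::create(B, C, HO, WO);
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_weights(HO, H, h0, h1, hw);
  up2_weights(WO, W, w0, w1v, ww);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho) {
      const double a = (1 - hw[ho]) * (1 - ww[wo]), b2 = hw[ho] * (1 - ww[wo]);
      const double c2 = (1 - hw[ho]) * ww[wo], d = hw[ho] * ww[wo];
      for (int c = 0; c < C; ++c)
        for (int b = 0; b < B; ++b) {
          const std::size_t base = b + (std::size_t)B * c;
          const double v =
            a * px[base + (std::size_t)B * C * (h0[ho] + (std::size_t)H * w0[wo])] +
            b2 * px[base + (std::size_t)B * C * (h1[ho] + (std::size_t)H * w0[wo])] +
            c2 * px[base + (std::size_t)B * C * (h0[ho] + (std::size_t)H * w1v[wo])] +
            d * px[base + (std::size_t)B * C * (h1[ho] + (std::size_t)H * w1v[wo])];
          po[b + (std::size_t)B * (c + (std::size_t)C * (ho + (std::size_t)HO * wo))] = v;
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_bw(NumericVector gout, IntegerVector xd) {
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int HO = 2 * H, WO = 2 * W;
  NumericVector gx((std::size_t)B * C * H * W);
  gx.attr("dim") = xd;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_weights(HO, H, h0, h1, hw);
  up2_weights(WO, W, w0, w1v, ww);
  const double* pg = REAL(gout);
  double* pgx = REAL(gx);
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho) {
      const double a = (1 - hw[ho]) * (1 - ww[wo]), b2 = hw[ho] * (1 - ww[wo]);
      const double c2 = (1 - hw[ho]) * ww[wo], d = hw[ho] * ww[wo];
      for (int c = 0; c < C; ++c)
        for (int b = 0; b < B; ++b) {
          const std::size_t base = b + (std::size_t)B * c;
          const double g =
            pg[b + (std::size_t)B * (c + (std::size_t)C * (ho + (std::size_t)HO * wo))];
          pgx[base + (std::size_t)B * C * (h0[ho] + (std::size_t)H * w0[wo])] += a * g;
          pgx[base + (std::size_t)B * C * (h1[ho] + (std::size_t)H * w0[wo])] += b2 * g;
          pgx[base + (std::size_t)B * C * (h0[ho] + (std::size_t)H * w1v[wo])] += c2 * g;
          pgx[base + (std::size_t)B * C * (h1[ho] + (std::size_t)H * w1v[wo])] += d * g;
        }
    }
  return gx;
}
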