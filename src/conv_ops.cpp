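#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Arrays are column-major with dims (H, W, C); element (h, w, c) lives at
// h + H*(w + W*c). Convolutions are stride-1 with symmetric zero padding of
// (k-1)/2 so the output geometry equals the input geometry (kernel sizes are
// validated to be odd on the R side).

// x: H x W x Cin, w: kh x kw x Cin x Cout, b: length Cout
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((R_xlen_t)H * W * Cout);
  const double *xp0 = x.begin(), *wp = w.begin(), *bp = b.begin();
  double *yp0 = y.begin();

  for (int co = 0; co < Cout; ++co) {
    double *yp = yp0 + (R_xlen_t)co * H * W;
    std::fill(yp, yp + (R_xlen_t)H * W, bp[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xp = xp0 + (R_xlen_t)ci * H * W;
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const double wv = wp[dh + kh * (dw + kw * (ci + Cin * co))];
          if (wv == 0.0) continue;
          // output (oh, ow) reads input (oh + dh - ph, ow + dw - pw)
          const int oh0 = std::max(0, ph - dh), oh1 = std::min(H - 1, H - 1 + ph - dh);
          const int ow0 = std::max(0, pw - dw), ow1 = std::min(W - 1, W - 1 + pw - dw);
          for (int ow = ow0; ow <= ow1; ++ow) {
            const double *xc = xp + (R_xlen_t)(ow + dw - pw) * H + (dh - ph);
            double *yc = yp + (R_xlen_t)ow * H;
            for (int oh = oh0; oh <= oh1; ++oh) yc[oh] += wv * xc[oh];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  return y;
}

// gradients of the same convolution; gy has dims (H, W, Cout)
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx((R_xlen_t)H * W * Cin), gw((R_xlen_t)kh * kw * Cin * Cout),
      gb(Cout);
  const double *xp0 = x.begin(), *wp = w.begin(), *gyp0 = gy.begin();
  double *gxp0 = gx.begin(), *gwp = gw.begin(), *gbp = gb.begin();

  for (int co = 0; co < Cout; ++co) {
    const double *gyp = gyp0 + (R_xlen_t)co * H * W;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) acc += gyp[i];
    gbp[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xp = xp0 + (R_xlen_t)ci * H * W;
      double *gxp = gxp0 + (R_xlen_t)ci * H * W;
      for (int dw = 0; dw < kw; ++dw) {
        for (int dh = 0; dh < kh; ++dh) {
          const double wv = wp[dh + kh * (dw + kw * (ci + Cin * co))];
          const int oh0 = std::max(0, ph - dh), oh1 = std::min(H - 1, H - 1 + ph - dh);
          const int ow0 = std::max(0, pw - dw), ow1 = std::min(W - 1, W - 1 + pw - dw);
          double gwv = 0.0;
          for (int ow = ow0; ow <= ow1; ++ow) {
            const double *xc = xp + (R_xlen_t)(ow + dw - pw) * H + (dh - ph);
            double *gxc = gxp + (R_xlen_t)(ow + dw - pw) * H + (dh - ph);
            const double *gyc = gyp + (R_xlen_t)ow * H;
            for (int oh = oh0; oh <= oh1; ++oh) {
              gwv += gyc[oh] * xc[oh];
              gxc[oh] += gyc[oh] * wv;
            }
          }
          gwp[dh + kh * (dw + kw * (ci + Cin * co))] += gwv;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max-pooling with argmax recording; H and W must be even.
// idx holds 1-based linear positions into x (the pooling indices reused by
// the decoder's unpooling).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xoff = (R_xlen_t)c * H * W, yoff = (R_xlen_t)c * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        R_xlen_t best = xoff + (R_xlen_t)(2 * ow) * H + 2 * oh;
        // candidates in column-major order: ties break to the first seen,
        // i.e. top-left, then bottom-left, top-right, bottom-right
        const R_xlen_t cand[4] = {best, best + 1, best + H, best + H + 1};
        double bv = xp[cand[0]];
        for (int k = 1; k < 4; ++k)
          if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
        yp[yoff + (R_xlen_t)ow * Ho + oh] = bv;
        ip[yoff + (R_xlen_t)ow * Ho + oh] = (int)(best + 1);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// scatter gy back to the recorded argmax positions of an (H, W, C) input
// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx, int H, int W,
                               int C) {
  NumericVector gx((R_xlen_t)H * W * C);
  double *gxp = gx.begin();
  const double *gyp = gy.begin();
  const int *ip = idx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[ip[i] - 1] += gyp[i];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

// unpooling forward: place values at recorded indices, zeros elsewhere
// [[Rcpp::export]]
NumericVector cpp_unpool2_fwd(NumericVector x, IntegerVector idx, int H, int W,
                              int C) {
  NumericVector y((R_xlen_t)H * W * C);
  double *yp = y.begin();
  const double *xp = x.begin();
  const int *ip = idx.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[ip[i] - 1] = xp[i];
  y.attr("dim") = IntegerVector::create(H, W, C);
  return y;
}

// unpooling backward: gather gradient from the recorded positions
// [[Rcpp::export]]
NumericVector cpp_unpool2_bwd(NumericVector gy, IntegerVector idx, int Ho, int Wo,
                              int C) {
  NumericVector gx((R_xlen_t)Ho * Wo * C);
  double *gxp = gx.begin();
  const double *gyp = gy.begin();
  const int *ip = idx.begin();
  const R_xlen_t n = gx.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[i] = gyp[ip[i] - 1];
  gx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return gx;
}
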