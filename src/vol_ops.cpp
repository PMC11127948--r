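#include <Rcpp.h>
#include <cfloat>
#include <vector>
using namespace Rcpp;

// Volumes are R arrays with dim (n, c, d, h, w), column-major, so the
// linear index of (n,c,d,h,w) (0-based) is n + N*(c + C*(d + D*(h + H*w))).
// Convolution is computed directly (no im2col): per (sample, output
// channel) the output block is accumulated tap by tap in an L1-resident
// buffer, with the valid output range per kernel offset precomputed so the
// inner loops carry no bounds checks.

static inline int out_extent(int in, int k, int stride, int pad, int dil) {
  int span = (k - 1) * dil + 1;
  return (in + 2 * pad - span) / stride + 1;
}

// valid output range [lo, hi] along one axis for kernel offset `off`
static inline void lohi(int off, int ext, int oext, int stride, int pad,
                        int dil, int &lo, int &hi) {
  int shift = off * dil - pad;
  lo = shift < 0 ? (-shift + stride - 1) / stride : 0;
  int num = ext - 1 - shift;
  hi = num < 0 ? -1 : num / stride;
  if (hi > oext - 1) hi = oext - 1;
}

// [[Rcpp::export]]
List cpp_conv3d_fw(NumericVector x, IntegerVector xdim, NumericVector w,
                   IntegerVector wdim, Nullable<NumericVector> bias,
                   int stride, int pad, int dil) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int CO = wdim[0], CI = wdim[1];
  const int KD = wdim[2], KH = wdim[3], KW = wdim[4];
  if (CI != C) stop("conv expects %d input channels, got %d", CI, C);
  const int OD = out_extent(D, KD, stride, pad, dil);
  const int OH = out_extent(H, KH, stride, pad, dil);
  const int OW = out_extent(W, KW, stride, pad, dil);
  if (OD < 1 || OH < 1 || OW < 1)
    stop("kernel span exceeds padded input extent");
  const R_xlen_t P = (R_xlen_t)OD * OH * OW;
  NumericVector y((R_xlen_t)N * CO * P);
  double *py = y.begin();
  const double *px = x.begin();
  const double *pw = w.begin();
  const R_xlen_t sC = (R_xlen_t)N * C;          // stride per depth step
  const R_xlen_t sD = sC * D, sH = sD * H;      // strides per h / w step
  const R_xlen_t dstep = sC * stride;
  const double *pb = nullptr;
  if (bias.isNotNull()) pb = NumericVector(bias).begin();
  // batch-inner accumulation buffer: index n + N*p (contiguous per voxel)
  std::vector<double> buf((R_xlen_t)N * P);
  for (int co = 0; co < CO; ++co) {
    std::fill(buf.begin(), buf.end(), pb ? pb[co] : 0.0);
    for (int ci = 0; ci < C; ++ci)
      for (int g = 0; g < KW; ++g)
        for (int b = 0; b < KH; ++b)
          for (int a = 0; a < KD; ++a) {
            const double wv =
                pw[co + (R_xlen_t)CO *
                            (ci + (R_xlen_t)CI *
                                      (a + (R_xlen_t)KD * (b + (R_xlen_t)KH * g)))];
            if (wv == 0.0) continue;
            int wlo, whi, hlo, hhi, dlo, dhi;
            lohi(g, W, OW, stride, pad, dil, wlo, whi);
            lohi(b, H, OH, stride, pad, dil, hlo, hhi);
            lohi(a, D, OD, stride, pad, dil, dlo, dhi);
            const int d0 = dlo * stride - pad + a * dil;
            for (int ow = wlo; ow <= whi; ++ow) {
              const int wpos = ow * stride - pad + g * dil;
              for (int oh = hlo; oh <= hhi; ++oh) {
                const int hpos = oh * stride - pad + b * dil;
                const double *src =
                    px + (R_xlen_t)N * ci + sD * hpos + sH * wpos + sC * d0;
                double *dst =
                    &buf[(R_xlen_t)N *
                         (dlo + (R_xlen_t)OD * (oh + (R_xlen_t)OH * ow))];
                for (int od = dlo; od <= dhi; ++od) {
                  for (int n = 0; n < N; ++n) dst[n] += wv * src[n];
                  src += dstep;
                  dst += N;
                }
              }
            }
          }
    double *dst = py + (R_xlen_t)N * co;
    const double *sp = buf.data();
    const R_xlen_t ystep = (R_xlen_t)N * CO;
    for (R_xlen_t p = 0; p < P; ++p) {
      for (int n = 0; n < N; ++n) dst[n] = sp[n];
      dst += ystep;
      sp += N;
    }
  }
  y.attr("odim") = IntegerVector::create(N, CO, OD, OH, OW);
  return List::create(_["y"] = y,
                      _["odim"] = IntegerVector::create(N, CO, OD, OH, OW));
}

// Weight gradient: gW[co,ci,a,b,g] = sum_n,p gy[n,co,p] * x[n,ci,src(p)].
// [[Rcpp::export]]
NumericVector cpp_conv3d_gw(NumericVector x, IntegerVector xdim,
                            NumericVector gy, IntegerVector wdim, int stride,
                            int pad, int dil) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int CO = wdim[0], CI = wdim[1];
  const int KD = wdim[2], KH = wdim[3], KW = wdim[4];
  const int OD = out_extent(D, KD, stride, pad, dil);
  const int OH = out_extent(H, KH, stride, pad, dil);
  const int OW = out_extent(W, KW, stride, pad, dil);
  const R_xlen_t P = (R_xlen_t)OD * OH * OW;
  NumericVector gw((R_xlen_t)CO * CI * KD * KH * KW);
  double *pg = gw.begin();
  const double *px = x.begin();
  const double *py = gy.begin();
  const R_xlen_t sC = (R_xlen_t)N * C;
  const R_xlen_t sD = sC * D, sH = sD * H;
  const R_xlen_t dstep = sC * stride;
  std::vector<double> gbuf((R_xlen_t)N * P); // gy[n, co, .], batch-inner
  for (int co = 0; co < CO; ++co) {
    {
      const double *src = py + (R_xlen_t)N * co;
      double *dst = gbuf.data();
      const R_xlen_t ystep = (R_xlen_t)N * CO;
      for (R_xlen_t p = 0; p < P; ++p) {
        for (int n = 0; n < N; ++n) dst[n] = src[n];
        src += ystep;
        dst += N;
      }
    }
    for (int ci = 0; ci < C; ++ci)
      for (int g = 0; g < KW; ++g)
        for (int b = 0; b < KH; ++b)
          for (int a = 0; a < KD; ++a) {
            int wlo, whi, hlo, hhi, dlo, dhi;
            lohi(g, W, OW, stride, pad, dil, wlo, whi);
            lohi(b, H, OH, stride, pad, dil, hlo, hhi);
            lohi(a, D, OD, stride, pad, dil, dlo, dhi);
            const int d0 = dlo * stride - pad + a * dil;
            double acc = 0.0;
            for (int ow = wlo; ow <= whi; ++ow) {
              const int wpos = ow * stride - pad + g * dil;
              for (int oh = hlo; oh <= hhi; ++oh) {
                const int hpos = oh * stride - pad + b * dil;
                const double *src =
                    px + (R_xlen_t)N * ci + sD * hpos + sH * wpos + sC * d0;
                const double *gp =
                    &gbuf[(R_xlen_t)N *
                          (dlo + (R_xlen_t)OD * (oh + (R_xlen_t)OH * ow))];
                for (int od = dlo; od <= dhi; ++od) {
                  for (int n = 0; n < N; ++n) acc += gp[n] * src[n];
                  src += dstep;
                  gp += N;
                }
              }
            }
            pg[co + (R_xlen_t)CO *
                        (ci + (R_xlen_t)CI *
                                  (a + (R_xlen_t)KD * (b + (R_xlen_t)KH * g)))] += acc;
          }
  }
  return gw;
}

// Input gradient: gx[n,ci,src(p)] += W[co,ci,tap] * gy[n,co,p].
// [[Rcpp::export]]
NumericVector cpp_conv3d_gx(NumericVector gy, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim, int stride,
                            int pad, int dil) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int CO = wdim[0], CI = wdim[1];
  const int KD = wdim[2], KH = wdim[3], KW = wdim[4];
  const int OD = out_extent(D, KD, stride, pad, dil);
  const int OH = out_extent(H, KH, stride, pad, dil);
  const int OW = out_extent(W, KW, stride, pad, dil);
  const R_xlen_t P = (R_xlen_t)OD * OH * OW;
  NumericVector gx((R_xlen_t)N * C * D * H * W);
  double *pgx = gx.begin();
  const double *py = gy.begin();
  const double *pw = w.begin();
  const R_xlen_t sC = (R_xlen_t)N * C;
  const R_xlen_t sD = sC * D, sH = sD * H;
  const R_xlen_t dstep = sC * stride;
  std::vector<double> gbuf((R_xlen_t)N * P);
  for (int co = 0; co < CO; ++co) {
    {
      const double *src = py + (R_xlen_t)N * co;
      double *dst = gbuf.data();
      const R_xlen_t ystep = (R_xlen_t)N * CO;
      for (R_xlen_t p = 0; p < P; ++p) {
        for (int n = 0; n < N; ++n) dst[n] = src[n];
        src += ystep;
        dst += N;
      }
    }
    for (int ci = 0; ci < C; ++ci)
      for (int g = 0; g < KW; ++g)
        for (int b = 0; b < KH; ++b)
          for (int a = 0; a < KD; ++a) {
            const double wv =
                pw[co + (R_xlen_t)CO *
                            (ci + (R_xlen_t)CI *
                                      (a + (R_xlen_t)KD * (b + (R_xlen_t)KH * g)))];
            if (wv == 0.0) continue;
            int wlo, whi, hlo, hhi, dlo, dhi;
            lohi(g, W, OW, stride, pad, dil, wlo, whi);
            lohi(b, H, OH, stride, pad, dil, hlo, hhi);
            lohi(a, D, OD, stride, pad, dil, dlo, dhi);
            const int d0 = dlo * stride - pad + a * dil;
            for (int ow = wlo; ow <= whi; ++ow) {
              const int wpos = ow * stride - pad + g * dil;
              for (int oh = hlo; oh <= hhi; ++oh) {
                const int hpos = oh * stride - pad + b * dil;
                double *dst =
                    pgx + (R_xlen_t)N * ci + sD * hpos + sH * wpos + sC * d0;
                const double *gp =
                    &gbuf[(R_xlen_t)N *
                          (dlo + (R_xlen_t)OD * (oh + (R_xlen_t)OH * ow))];
                for (int od = dlo; od <= dhi; ++od) {
                  for (int n = 0; n < N; ++n) dst[n] += wv * gp[n];
                  dst += dstep;
                  gp += N;
                }
              }
            }
          }
  }
  return gx;
}

// Joint max/average pooling pass. Padding cells never enter a window: the
// max is over in-bounds cells only and the average divisor is the in-bounds
// count ("count includes only covered cells").
// [[Rcpp::export]]
List cpp_pool3d_fw(NumericVector x, IntegerVector xdim, IntegerVector kernel,
                   int stride, int pad) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int KD = kernel[0], KH = kernel[1], KW = kernel[2];
  const int OD = out_extent(D, KD, stride, pad, 1);
  const int OH = out_extent(H, KH, stride, pad, 1);
  const int OW = out_extent(W, KW, stride, pad, 1);
  if (OD < 1 || OH < 1 || OW < 1)
    stop("pooling window exceeds padded input extent");
  const R_xlen_t no = (R_xlen_t)N * C * OD * OH * OW;
  NumericVector ymax(no), yavg(no);
  IntegerVector argmax(no);  // 1-based linear index into x
  const double *px = x.begin();
  for (int w0 = 0; w0 < OW; ++w0)
    for (int h0 = 0; h0 < OH; ++h0)
      for (int d0 = 0; d0 < OD; ++d0)
        for (int c = 0; c < C; ++c)
          for (int n = 0; n < N; ++n) {
            double best = -DBL_MAX, acc = 0.0;
            R_xlen_t besti = -1;
            int cnt = 0;
            for (int g = 0; g < KW; ++g) {
              const int w = w0 * stride - pad + g;
              if (w < 0 || w >= W) continue;
              for (int b = 0; b < KH; ++b) {
                const int h = h0 * stride - pad + b;
                if (h < 0 || h >= H) continue;
                for (int a = 0; a < KD; ++a) {
                  const int d = d0 * stride - pad + a;
                  if (d < 0 || d >= D) continue;
                  const R_xlen_t ix =
                      (R_xlen_t)n +
                      (R_xlen_t)N *
                          (c + (R_xlen_t)C *
                                   (d + (R_xlen_t)D * (h + (R_xlen_t)H * w)));
                  const double v = px[ix];
                  acc += v;
                  ++cnt;
                  if (v > best) { best = v; besti = ix; }
                }
              }
            }
            const R_xlen_t oy =
                (R_xlen_t)n +
                (R_xlen_t)N *
                    (c + (R_xlen_t)C *
                             (d0 + (R_xlen_t)OD * (h0 + (R_xlen_t)OH * w0)));
            ymax[oy] = best;
            yavg[oy] = acc / cnt;
            argmax[oy] = (int)(besti + 1);
          }
  IntegerVector odim = IntegerVector::create(N, C, OD, OH, OW);
  return List::create(_["max"] = ymax, _["avg"] = yavg, _["argmax"] = argmax,
                      _["odim"] = odim);
}

// Scatter gradient to the argmax positions (max-pool adjoint).
// [[Rcpp::export]]
NumericVector cpp_pool3d_bw_max(IntegerVector argmax, NumericVector gy,
                                R_xlen_t xlen) {
  NumericVector gx(xlen);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i] - 1] += gy[i];
  return gx;
}

// Spread gradient uniformly over each window's in-bounds cells
// (average-pool adjoint).
// [[Rcpp::export]]
NumericVector cpp_pool3d_bw_avg(NumericVector gy, IntegerVector xdim,
                                IntegerVector kernel, int stride, int pad) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int KD = kernel[0], KH = kernel[1], KW = kernel[2];
  const int OD = out_extent(D, KD, stride, pad, 1);
  const int OH = out_extent(H, KH, stride, pad, 1);
  const int OW = out_extent(W, KW, stride, pad, 1);
  NumericVector gx((R_xlen_t)N * C * D * H * W);
  double *pg = gx.begin();
  const double *py = gy.begin();
  for (int w0 = 0; w0 < OW; ++w0)
    for (int h0 = 0; h0 < OH; ++h0)
      for (int d0 = 0; d0 < OD; ++d0)
        for (int c = 0; c < C; ++c)
          for (int n = 0; n < N; ++n) {
            int cnt = 0;
            for (int g = 0; g < KW; ++g) {
              const int w = w0 * stride - pad + g;
              if (w < 0 || w >= W) continue;
              for (int b = 0; b < KH; ++b) {
                const int h = h0 * stride - pad + b;
                if (h < 0 || h >= H) continue;
                for (int a = 0; a < KD; ++a) {
                  const int d = d0 * stride - pad + a;
                  if (d >= 0 && d < D) ++cnt;
                }
              }
            }
            const double share =
                py[(R_xlen_t)n +
                   (R_xlen_t)N *
                       (c + (R_xlen_t)C *
                                (d0 + (R_xlen_t)OD * (h0 + (R_xlen_t)OH * w0)))] /
                cnt;
            for (int g = 0; g < KW; ++g) {
              const int w = w0 * stride - pad + g;
              if (w < 0 || w >= W) continue;
              for (int b = 0; b < KH; ++b) {
                const int h = h0 * stride - pad + b;
                if (h < 0 || h >= H) continue;
                for (int a = 0; a < KD; ++a) {
                  const int d = d0 * stride - pad + a;
                  if (d < 0 || d >= D) continue;
                  pg[(R_xlen_t)n +
                     (R_xlen_t)N *
                         (c + (R_xlen_t)C *
                                  (d + (R_xlen_t)D * (h + (R_xlen_t)H * w)))] +=
                      share;
                }
              }
            }
          }
  return gx;
}
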