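// Minimal convolution primitives backing the two CNNs (scatter estimation
// and residual dose-map learning). Stride is always 1; 2-D convolutions use
// zero padding that preserves the spatial size; 3-D convolutions preserve
// the in-plane size and are valid (unpadded) along the slice axis, which is
// how an 11-slice input pack collapses to a single output slice.
//
// Array layouts follow R column-major conventions:
//   conv2d  x: (H, W, C)        w: (kh, kw, C, K)     y: (H, W, K)
//   conv3d  x: (H, W, D, C)     w: (kh, kw, kd, C, K) y: (H, W, D-kd+1, K)
//
// Loops are organised so the innermost pass runs over contiguous column
// segments with precomputed valid ranges (no per-element bounds checks).

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// valid output range for one kernel offset: 0 <= o + k - p < N
static inline void valid_range(int N, int k, int p, int& lo, int& hi) {
  lo = std::max(0, p - k);
  hi = std::min(N, N + p - k);
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, IntegerVector xd,
                             IntegerVector wd) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector y((long)H * W * K);
  const double* X = x.begin();
  const double* Wt = w.begin();
  double* Y = y.begin();
  for (int k = 0; k < K; ++k) {
    double* Yk = Y + (long)k * H * W;
    std::fill(Yk, Yk + (long)H * W, b[k]);
    for (int c = 0; c < C; ++c) {
      const double* Xc = X + (long)c * H * W;
      const double* Wc = Wt + ((long)k * C + c) * kh * kw;
      for (int kj = 0; kj < kw; ++kj) {
        int oj_lo, oj_hi; valid_range(W, kj, pw, oj_lo, oj_hi);
        for (int ki = 0; ki < kh; ++ki) {
          int oi_lo, oi_hi; valid_range(H, ki, ph, oi_lo, oi_hi);
          const double wv = Wc[(long)kj * kh + ki];
          if (wv == 0.0) continue;
          for (int oj = oj_lo; oj < oj_hi; ++oj) {
            const double* xcol = Xc + (long)(oj + kj - pw) * H + (ki - ph);
            double* ycol = Yk + (long)oj * H;
            for (int oi = oi_lo; oi < oi_hi; ++oi)
              ycol[oi] += wv * xcol[oi];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, K);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector xd, IntegerVector wd) {
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector gx((long)H * W * C), gw(w.size()), gb(K);
  const double* X = x.begin();
  const double* Wt = w.begin();
  const double* GY = gy.begin();
  double* GX = gx.begin();
  double* GW = gw.begin();
  for (int k = 0; k < K; ++k) {
    const double* GYk = GY + (long)k * H * W;
    double s = 0.0;
    for (long i = 0; i < (long)H * W; ++i) s += GYk[i];
    gb[k] = s;
    for (int c = 0; c < C; ++c) {
      const double* Xc = X + (long)c * H * W;
      double* GXc = GX + (long)c * H * W;
      const double* Wc = Wt + ((long)k * C + c) * kh * kw;
      double* GWc = GW + ((long)k * C + c) * kh * kw;
      for (int kj = 0; kj < kw; ++kj) {
        int oj_lo, oj_hi; valid_range(W, kj, pw, oj_lo, oj_hi);
        for (int ki = 0; ki < kh; ++ki) {
          int oi_lo, oi_hi; valid_range(H, ki, ph, oi_lo, oi_hi);
          const double wv = Wc[(long)kj * kh + ki];
          double acc = 0.0;
          for (int oj = oj_lo; oj < oj_hi; ++oj) {
            const double* xcol = Xc + (long)(oj + kj - pw) * H + (ki - ph);
            double* gxcol = GXc + (long)(oj + kj - pw) * H + (ki - ph);
            const double* gcol = GYk + (long)oj * H;
            for (int oi = oi_lo; oi < oi_hi; ++oi) {
              const double g = gcol[oi];
              acc += xcol[oi] * g;
              gxcol[oi] += wv * g;
            }
          }
          GWc[(long)kj * kh + ki] += acc;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, IntegerVector xd,
                             IntegerVector wd) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], kd = wd[2], K = wd[4];
  const int ph = kh / 2, pw = kw / 2;
  const int Dout = D - kd + 1;
  if (Dout < 1) stop("conv3d: kernel depth exceeds input depth");
  NumericVector y((long)H * W * Dout * K);
  const double* X = x.begin();
  const double* Wt = w.begin();
  double* Y = y.begin();
  for (int k = 0; k < K; ++k) {
    double* Yk = Y + (long)k * H * W * Dout;
    std::fill(Yk, Yk + (long)H * W * Dout, b[k]);
    for (int od = 0; od < Dout; ++od) {
      double* Ys = Yk + (long)od * W * H;
      for (int c = 0; c < C; ++c) {
        for (int dd = 0; dd < kd; ++dd) {
          const double* Xs = X + ((long)c * D + od + dd) * (long)W * H;
          const double* Ws = Wt + ((((long)k * C + c) * kd + dd) * kw) * kh;
          for (int kj = 0; kj < kw; ++kj) {
            int oj_lo, oj_hi; valid_range(W, kj, pw, oj_lo, oj_hi);
            for (int ki = 0; ki < kh; ++ki) {
              int oi_lo, oi_hi; valid_range(H, ki, ph, oi_lo, oi_hi);
              const double wv = Ws[(long)kj * kh + ki];
              if (wv == 0.0) continue;
              for (int oj = oj_lo; oj < oj_hi; ++oj) {
                const double* xcol = Xs + (long)(oj + kj - pw) * H + (ki - ph);
                double* ycol = Ys + (long)oj * H;
                for (int oi = oi_lo; oi < oi_hi; ++oi)
                  ycol[oi] += wv * xcol[oi];
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Dout, K);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector xd, IntegerVector wd) {
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  const int kh = wd[0], kw = wd[1], kd = wd[2], K = wd[4];
  const int ph = kh / 2, pw = kw / 2;
  const int Dout = D - kd + 1;
  NumericVector gx((long)H * W * D * C), gw(w.size()), gb(K);
  const double* X = x.begin();
  const double* Wt = w.begin();
  const double* GY = gy.begin();
  double* GX = gx.begin();
  double* GW = gw.begin();
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    for (long i = 0; i < (long)H * W * Dout; ++i)
      s += GY[(long)k * H * W * Dout + i];
    gb[k] = s;
    for (int od = 0; od < Dout; ++od) {
      const double* GYs = GY + ((long)k * Dout + od) * (long)W * H;
      for (int c = 0; c < C; ++c) {
        for (int dd = 0; dd < kd; ++dd) {
          const double* Xs = X + ((long)c * D + od + dd) * (long)W * H;
          double* GXs = GX + ((long)c * D + od + dd) * (long)W * H;
          const double* Ws = Wt + ((((long)k * C + c) * kd + dd) * kw) * kh;
          double* GWs = GW + ((((long)k * C + c) * kd + dd) * kw) * kh;
          for (int kj = 0; kj < kw; ++kj) {
            int oj_lo, oj_hi; valid_range(W, kj, pw, oj_lo, oj_hi);
            for (int ki = 0; ki < kh; ++ki) {
              int oi_lo, oi_hi; valid_range(H, ki, ph, oi_lo, oi_hi);
              const double wv = Ws[(long)kj * kh + ki];
              double acc = 0.0;
              for (int oj = oj_lo; oj < oj_hi; ++oj) {
                const double* xcol = Xs + (long)(oj + kj - pw) * H + (ki - ph);
                double* gxcol = GXs + (long)(oj + kj - pw) * H + (ki - ph);
                const double* gcol = GYs + (long)oj * H;
                for (int oi = oi_lo; oi < oi_hi; ++oi) {
                  const double g = gcol[oi];
                  acc += xcol[oi] * g;
                  gxcol[oi] += wv * g;
                }
              }
              GWs[(long)kj * kh + ki] += acc;
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
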