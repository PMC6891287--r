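#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Keys cubic convolution kernel, a = -0.5 (Catmull-Rom); sums to 1 on the
// integer lattice so constant images are preserved exactly.
static inline double cubic_kernel(double x) {
  const double a = -0.5;
  x = std::fabs(x);
  if (x < 1.0) return ((a + 2.0) * x - (a + 3.0)) * x * x + 1.0;
  if (x < 2.0) return (((x - 5.0) * x + 8.0) * x - 4.0) * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable bicubic resampling of a numeric matrix. Pixel centres follow the
// half-pixel convention: destination pixel i samples the source at
// (i + 0.5) * src/dst - 0.5, so an identity-size resize reproduces the input.
// [[Rcpp::export]]
NumericMatrix resize_bicubic_cpp(NumericMatrix src, int out_h, int out_w) {
  const int in_h = src.nrow(), in_w = src.ncol();
  const double sy = static_cast<double>(in_h) / out_h;
  const double sx = static_cast<double>(in_w) / out_w;

  // horizontal pass: in_h x out_w
  NumericMatrix tmp(in_h, out_w);
  for (int j = 0; j < out_w; ++j) {
    const double xs = (j + 0.5) * sx - 0.5;
    const int x0 = static_cast<int>(std::floor(xs)) - 1;
    double wgt[4];
    for (int t = 0; t < 4; ++t) wgt[t] = cubic_kernel(xs - (x0 + t));
    for (int i = 0; i < in_h; ++i) {
      double acc = 0.0;
      for (int t = 0; t < 4; ++t)
        acc += wgt[t] * src(i, clampi(x0 + t, 0, in_w - 1));
      tmp(i, j) = acc;
    }
  }

  // vertical pass: out_h x out_w
  NumericMatrix out(out_h, out_w);
  for (int i = 0; i < out_h; ++i) {
    const double ys = (i + 0.5) * sy - 0.5;
    const int y0 = static_cast<int>(std::floor(ys)) - 1;
    double wgt[4];
    for (int t = 0; t < 4; ++t) wgt[t] = cubic_kernel(ys - (y0 + t));
    for (int j = 0; j < out_w; ++j) {
      double acc = 0.0;
      for (int t = 0; t < 4; ++t)
        acc += wgt[t] * tmp(clampi(y0 + t, 0, in_h - 1), j);
      out(i, j) = acc;
    }
  }
  return out;
}

// Block-average downsampling of an H x W plane by an integer factor.
// [[Rcpp::export]]
NumericMatrix downsample_avg_cpp(NumericMatrix src, int factor) {
  const int out_h = src.nrow() / factor, out_w = src.ncol() / factor;
  NumericMatrix out(out_h, out_w);
  const double inv = 1.0 / (factor * factor);
  for (int j = 0; j < out_w; ++j)
    for (int i = 0; i < out_h; ++i) {
      double acc = 0.0;
      for (int dj = 0; dj < factor; ++dj)
        for (int di = 0; di < factor; ++di)
          acc += src(i * factor + di, j * factor + dj);
      out(i, j) = acc * inv;
    }
  return out;
}
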