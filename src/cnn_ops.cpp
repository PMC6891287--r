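#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Minimal CPU kernels for the reference CNN. Tensors are R arrays in
// column-major (H, W, C) layout; weights are (k, k, Cin, Cout). The
// convolution loops are organized as shifted-plane accumulations so the
// innermost loop runs contiguously down image columns.

// Same-padded 2-D convolution (zero padding (k-1)/2), k odd.
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector wt, NumericVector b,
                             IntegerVector dimx, IntegerVector dimw) {
  const int H = dimx[0], W = dimx[1], Cin = dimx[2];
  const int K = dimw[0], Cout = dimw[3];
  const int pad = (K - 1) / 2;
  NumericVector out(H * W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *px = x.begin(), *pw = wt.begin();
  double *po = out.begin();
  for (int co = 0; co < Cout; ++co) {
    double *oc = po + (R_xlen_t)H * W * co;
    std::fill(oc, oc + (R_xlen_t)H * W, b[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + (R_xlen_t)H * W * ci;
      for (int kw = 0; kw < K; ++kw) {
        const int dwv = kw - pad;
        const int w0 = std::max(0, -dwv), w1 = std::min(W, W - dwv);
        for (int kh = 0; kh < K; ++kh) {
          const int dh = kh - pad;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double wv = pw[kh + K * (kw + K * (ci + Cin * co))];
          if (wv == 0.0) continue;
          for (int w = w0; w < w1; ++w) {
            double *od = oc + (R_xlen_t)H * w + h0;
            const double *xs = xc + (R_xlen_t)H * (w + dwv) + h0 + dh;
            for (int h = h0; h < h1; ++h) *od++ += wv * *xs++;
          }
        }
      }
    }
  }
  return out;
}

// Gradients of the same-padded convolution w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector wt, NumericVector dout,
                    IntegerVector dimx, IntegerVector dimw) {
  const int H = dimx[0], W = dimx[1], Cin = dimx[2];
  const int K = dimw[0], Cout = dimw[3];
  const int pad = (K - 1) / 2;
  NumericVector dx(x.size()), dw(wt.size()), db(Cout);
  dx.attr("dim") = dimx;
  dw.attr("dim") = dimw;
  const double *px = x.begin(), *pw = wt.begin(), *pg = dout.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gc = pg + (R_xlen_t)H * W * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) acc += gc[i];
    db[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + (R_xlen_t)H * W * ci;
      double *dxc = pdx + (R_xlen_t)H * W * ci;
      for (int kw = 0; kw < K; ++kw) {
        const int dwv = kw - pad;
        const int w0 = std::max(0, -dwv), w1 = std::min(W, W - dwv);
        for (int kh = 0; kh < K; ++kh) {
          const int dh = kh - pad;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int wi = kh + K * (kw + K * (ci + Cin * co));
          const double wv = pw[wi];
          double wacc = 0.0;
          for (int w = w0; w < w1; ++w) {
            const double *gd = gc + (R_xlen_t)H * w + h0;
            const double *xs = xc + (R_xlen_t)H * (w + dwv) + h0 + dh;
            double *dxs = dxc + (R_xlen_t)H * (w + dwv) + h0 + dh;
            for (int h = h0; h < h1; ++h) {
              const double g = *gd++;
              wacc += g * *xs++;
              *dxs++ += g * wv;
            }
          }
          pdw[wi] += wacc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling with stride 2; returns pooled values and flat argmax
// indices (1-based into the input array) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector dimx) {
  const int H = dimx[0], W = dimx[1], C = dimx[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector arg(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = -1e300;
        int bi = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const int ii = (2 * h + dh) + H * ((2 * w + dw) + W * c);
            if (x[ii] > best) { best = x[ii]; bi = ii; }
          }
        const int oi = h + Ho * (w + Wo * c);
        out[oi] = best;
        arg[oi] = bi + 1;
      }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(IntegerVector argmax, NumericVector dout,
                               IntegerVector dimx) {
  NumericVector dx(dimx[0] * dimx[1] * dimx[2]);
  dx.attr("dim") = dimx;
  for (int i = 0; i < argmax.size(); ++i) dx[argmax[i] - 1] += dout[i];
  return dx;
}
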