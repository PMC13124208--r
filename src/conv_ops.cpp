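// im2col-based 2-D convolution kernels for the residual attention network.
// Tensors follow R's column-major array layout: activations are
// (H, W, C, N) and filters (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one image (H x W x C slab) into the im2col matrix
// (kh*kw*Cin) x (Ho*Wo). Out-of-range taps read zero padding.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        int row = p + kh * (q + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + q;
          bool win = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + p;
            double v = 0.0;
            if (win && hi >= 0 && hi < H) v = xc[hi + (size_t)wi * H];
            cols(row, ho + (size_t)wo * Ho) = v;
          }
        }
      }
    }
  }
}

// Scatter-add a cols matrix back onto the (padded-removed) input gradient.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        int row = p + kh * (q + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + q;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + p;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)wi * H] += cols(row, ho + (size_t)wo * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d_forward: channel mismatch");
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  // filters as (Cout) x (kh*kw*Cin)
  arma::mat Wm(kh * kw * Cin, Cout);
  std::copy(w.begin(), w.end(), Wm.memptr());
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    arma::mat out = cols.t() * Wm;  // (Ho*Wo) x Cout
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double b = bias[co];
      const double* src = out.colptr(co);
      double* dst = yp + (size_t)co * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dst[i] = src[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat Wm(kh * kw * Cin, Cout);
  std::copy(w.begin(), w.end(), Wm.memptr());
  arma::mat dWm(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat cols(kh * kw * Cin, (size_t)Ho * Wo);
  arma::mat dyM((size_t)Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
    std::copy(dyp, dyp + (size_t)Ho * Wo * Cout, dyM.memptr());
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    dWm += cols * dyM;
    db += arma::sum(dyM, 0).t();
    arma::mat dcols = Wm * dyM.t();  // (kh*kw*Cin) x (Ho*Wo)
    col2im(dcols, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  NumericVector dwOut(dWm.memptr(), dWm.memptr() + dWm.n_elem);
  dwOut.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwOut,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
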