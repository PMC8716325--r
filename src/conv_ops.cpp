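// GEMM-backed 2-D convolution primitives for the segmentation network.
// Tensor layout follows R's column-major arrays: dims (H, W, C, N).
// Weight layout: (k, k, Cin, Cout). All strides/paddings are symmetric.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather input windows of one sample into a (Ho*Wo) x (k*k*Cin) matrix whose
// column order matches the flattened (k, k, Cin) weight layout.
static void im2col(const double* x, int H, int W, int Cin,
                   int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  cols.zeros(Ho * Wo, k * k * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            cols(ho + Ho * wo, q) = x[h + H * (w + W * ci)];
          }
        }
      }
    }
  }
}

// Scatter-add of the column gradient back onto the input gradient.
static void col2im(const arma::mat& gcols, int H, int W, int Cin,
                   int k, int stride, int pad, double* gx) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            gx[h + H * (w + W * ci)] += gcols(ho + Ho * wo, q);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: input channels do not match kernel");
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat cols;
  const int xs = H * W * Cin, ys = Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, Cin, k, stride, pad, cols);
    arma::mat ym(y.begin() + n * ys, Ho * Wo, Cout, false, true);
    ym = cols * wm;
    for (int co = 0; co < Cout; ++co) ym.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat gwm(gw.begin(), k * k * Cin, Cout, false, true);
  arma::mat cols;
  const int xs = H * W * Cin, ys = Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, Cin, k, stride, pad, cols);
    arma::mat gym(const_cast<double*>(gy.begin()) + n * ys,
                  Ho * Wo, Cout, false, true);
    gwm += cols.t() * gym;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gym.col(co));
    arma::mat gcols = gym * wm.t();
    col2im(gcols, H, W, Cin, k, stride, pad, gx.begin() + n * xs);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution with kernel 2, stride 2 (the only decoder
// upsampling used): output windows are disjoint, so no accumulation races.
// [[Rcpp::export(name = ".tconv2_fw")]]
NumericVector tconv2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != Cin) stop("tconv2: bad kernel dims");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  // wm2: (Cin) x (4*Cout), column d + 4*co holds W[ki, kj, ., co], d = ki+2*kj
  arma::mat wm2(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int d = 0; d < 4; ++d)
        wm2(ci, d + 4 * co) = w[d + 4 * ci + 4 * Cin * co];
  const int xs = H * W * Cin, ys = Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + n * xs, H * W, Cin, false, true);
    arma::mat prod = xm * wm2;  // (H*W) x (4*Cout)
    double* yp = y.begin() + n * ys;
    for (int co = 0; co < Cout; ++co) {
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          const int d = ki + 2 * kj;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yp[(2 * i + ki) + Ho * ((2 * j + kj) + Wo * co)] =
                prod(i + H * j, d + 4 * co) + b[co];
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv2_bw")]]
List tconv2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat wm2(Cin, 4 * Cout), gwm2(Cin, 4 * Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int d = 0; d < 4; ++d)
        wm2(ci, d + 4 * co) = w[d + 4 * ci + 4 * Cin * co];
  const int xs = H * W * Cin, ys = Ho * Wo * Cout;
  arma::mat gprod(H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* gyp = gy.begin() + n * ys;
    for (int co = 0; co < Cout; ++co)
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          const int d = ki + 2 * kj;
          double bsum = 0.0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = gyp[(2 * i + ki) + Ho * ((2 * j + kj) + Wo * co)];
              gprod(i + H * j, d + 4 * co) = g;
              bsum += g;
            }
          gb[co] += bsum;
        }
    arma::mat xm(const_cast<double*>(x.begin()) + n * xs, H * W, Cin, false, true);
    arma::mat gxm(gx.begin() + n * xs, H * W, Cin, false, true);
    gxm += gprod * wm2.t();
    gwm2 += xm.t() * gprod;
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int d = 0; d < 4; ++d)
        gw[d + 4 * ci + 4 * Cin * co] = gwm2(ci, d + 4 * co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
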