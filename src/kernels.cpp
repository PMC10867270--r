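// Dense compute kernels for the segmentation network.
// Tensor layout everywhere: column-major R arrays H x W x C x N
// (spatial fastest, batch slowest); conv weights kh x kw x Cin x Cout,
// which viewed as a (kh*kw*Cin) x Cout matrix is exactly the GEMM operand.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold one sample into M (K x Ho*Wo), K = kh*kw*C; out-of-range taps are 0.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int ph, int pw, int d,
                   int Ho, int Wo, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int win = ow - pw + j * d;
          double* Mcol0 = M.colptr(0);
          if (win < 0 || win >= W) {
            for (int oh = 0; oh < Ho; ++oh)
              M.at(k, (std::size_t)oh + (std::size_t)Ho * ow) = 0.0;
          } else {
            const double* xcol = xc + (std::size_t)H * win;
            for (int oh = 0; oh < Ho; ++oh) {
              const int hin = oh - ph + i * d;
              M.at(k, (std::size_t)oh + (std::size_t)Ho * ow) =
                  (hin >= 0 && hin < H) ? xcol[hin] : 0.0;
            }
          }
          (void)Mcol0;
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add M back onto the (padded-window) input grid.
static void col2im_add(const arma::mat& M, double* gx, int H, int W, int C,
                       int kh, int kw, int ph, int pw, int d,
                       int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int win = ow - pw + j * d;
          if (win < 0 || win >= W) continue;
          double* xcol = xc + (std::size_t)H * win;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hin = oh - ph + i * d;
            if (hin >= 0 && hin < H)
              xcol[hin] += M.at(k, (std::size_t)oh + (std::size_t)Ho * ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int ph, int pw, int d) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  const int Ho = H + 2 * ph - d * (kh - 1), Wo = W + 2 * pw - d * (kw - 1);
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel/dilation larger than padded input");
  const int K = kh * kw * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((std::size_t)Ho * Wo * Cout * N);
  arma::mat M(K, (std::size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, ph, pw, d,
           Ho, Wo, M);
    arma::mat Y(y.begin() + (std::size_t)Ho * Wo * Cout * n,
                (std::size_t)Ho * Wo, Cout, false, true);
    Y = M.t() * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int ph, int pw, int d, bool need_gx) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  const int Ho = H + 2 * ph - d * (kh - 1), Wo = W + 2 * pw - d * (kw - 1);
  const int K = kh * kw * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat GW(K, Cout, arma::fill::zeros);
  arma::vec GB(Cout, arma::fill::zeros);
  NumericVector gx(need_gx ? (std::size_t)H * W * C * N : (std::size_t)1);
  arma::mat M(K, (std::size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double*>(gy.begin()) + (std::size_t)Ho * Wo * Cout * n,
                (std::size_t)Ho * Wo, Cout, false, true);
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, ph, pw, d,
           Ho, Wo, M);
    GW += M * G;
    GB += arma::sum(G, 0).t();
    if (need_gx) {
      arma::mat Gcol = Wm * G.t();  // K x HoWo
      col2im_add(Gcol, gx.begin() + (std::size_t)H * W * C * n, H, W, C, kh,
                 kw, ph, pw, d, Ho, Wo);
    }
  }
  NumericVector gw(GW.begin(), GW.end());
  gw.attr("dim") = wdim;
  if (need_gx) gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xdim = x.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  std::size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t base = (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++t) {
          std::size_t best = base + (std::size_t)(2 * oh) + (std::size_t)H * (2 * ow);
          double bv = x[best];
          const int hh[2] = {2 * oh, 2 * oh + 1}, ww[2] = {2 * ow, 2 * ow + 1};
          for (int a = 0; a < 2; ++a)
            for (int b = 0; b < 2; ++b) {
              std::size_t p = base + (std::size_t)hh[a] + (std::size_t)H * ww[b];
              if (x[p] > bv) { bv = x[p]; best = p; }
            }
          y[t] = bv;
          idx[t] = (int)best;  // fits: tensors here stay < 2^31 elements
        }
    }
  // y is filled in (oh, ow) inner order per (c, n) == column-major (Ho,Wo,C,N)
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy,
                               IntegerVector xdim) {
  NumericVector gx((std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[idx[t]] += gy[t];
  gx.attr("dim") = xdim;
  return gx;
}

static void up2_axes(int n, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& w1) {
  // align_corners = false mapping: src = (dst + 0.5)/2 - 0.5, clamped
  i0.resize(2 * n); i1.resize(2 * n); w1.resize(2 * n);
  for (int o = 0; o < 2 * n; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > n - 1) s = n - 1;
    int f = (int)std::floor(s);
    if (f > n - 2) f = n - 2;
    if (f < 0) f = 0;
    i0[o] = f; i1[o] = (n > 1) ? f + 1 : 0;
    w1[o] = (n > 1) ? s - f : 0.0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xdim = x.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_axes(H, h0, h1, hw);
  up2_axes(W, w0, w1v, ww);
  NumericVector y((std::size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      double* yc = y.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        const double b = ww[ow];
        const double* xl = xc + (std::size_t)H * w0[ow];
        const double* xr = xc + (std::size_t)H * w1v[ow];
        double* ycol = yc + (std::size_t)Ho * ow;
        for (int oh = 0; oh < Ho; ++oh) {
          const double a = hw[oh];
          ycol[oh] = (1 - a) * (1 - b) * xl[h0[oh]] + a * (1 - b) * xl[h1[oh]] +
                     (1 - a) * b * xr[h0[oh]] + a * b * xr[h1[oh]];
        }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  up2_axes(H, h0, h1, hw);
  up2_axes(W, w0, w1v, ww);
  NumericVector gx((std::size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = gx.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      const double* yc =
          gy.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        const double b = ww[ow];
        double* xl = xc + (std::size_t)H * w0[ow];
        double* xr = xc + (std::size_t)H * w1v[ow];
        const double* ycol = yc + (std::size_t)Ho * ow;
        for (int oh = 0; oh < Ho; ++oh) {
          const double a = hw[oh], g = ycol[oh];
          xl[h0[oh]] += (1 - a) * (1 - b) * g;
          xl[h1[oh]] += a * (1 - b) * g;
          xr[h0[oh]] += (1 - a) * b * g;
          xr[h1[oh]] += a * b * g;
        }
      }
    }
  gx.attr("dim") = xdim;
  return gx;
}
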