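// Dense CPU kernels for the segmentation network.
//
// Array layout follows R's column-major convention throughout:
// feature maps are [H, W, C, N], convolution weights [k, k, Cin, Cout].
// Convolutions are cross-correlations with zero padding k %/% 2 ("same"
// for stride 1); im2col + BLAS gemm via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill M (k*k*C x oh*ow) with patches of one sample; column index = oy + oh*ox.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int oh, int ow, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int ox = 0; ox < ow; ++ox) {
          const int in_x = ox * stride - pad + kj;
          double* Mcol = M.memptr() + (size_t)M.n_rows * (size_t)(oh * ox) + r;
          if (in_x < 0 || in_x >= W) {
            for (int oy = 0; oy < oh; ++oy) Mcol[(size_t)M.n_rows * oy] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * in_x;
          for (int oy = 0; oy < oh; ++oy) {
            const int in_y = oy * stride - pad + ki;
            Mcol[(size_t)M.n_rows * oy] =
              (in_y >= 0 && in_y < H) ? xcol[in_y] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient back onto the input plane.
static void col2im(const arma::mat& M, double* gx, int H, int W, int C,
                   int k, int stride, int pad, int oh, int ow) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int ox = 0; ox < ow; ++ox) {
          const int in_x = ox * stride - pad + kj;
          if (in_x < 0 || in_x >= W) continue;
          const double* Mcol = M.memptr() + (size_t)M.n_rows * (size_t)(oh * ox) + r;
          double* gcol = gc + (size_t)H * in_x;
          for (int oy = 0; oy < oh; ++oy) {
            const int in_y = oy * stride - pad + ki;
            if (in_y >= 0 && in_y < H)
              gcol[in_y] += Mcol[(size_t)M.n_rows * oy];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b, int stride) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int pad = k / 2;
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int ohow = oh * ow;

  NumericVector y((size_t)ohow * Cout * N);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat M(k * k * C, ohow);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, oh, ow, M);
    arma::mat Yt(y.begin() + (size_t)n * ohow * Cout, ohow, Cout, false, true);
    Yt = M.t() * Wm;
    for (int co = 0; co < Cout; ++co) Yt.col(co) += b[co];
  }
  y.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy, int stride, bool need_gx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  const int pad = k / 2;
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int ohow = oh * ow;

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector gw((size_t)k * k * Cin * Cout);
  NumericVector gb(Cout);
  NumericVector gx(need_gx ? (size_t)H * W * C * N : (size_t)0);
  arma::mat Gw(gw.begin(), k * k * Cin, Cout, false, true);
  arma::vec Gb(gb.begin(), Cout, false, true);

  arma::mat M(k * k * C, ohow);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, oh, ow, M);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * ohow * Cout,
                 ohow, Cout, false, true);
    Gw += M * Gy;
    Gb += arma::sum(Gy, 0).t();
    if (need_gx) {
      arma::mat Mg = Wm * Gy.t();  // (k*k*C) x ohow
      col2im(Mg, gx.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, oh, ow);
    }
  }
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  if (need_gx) gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; windows clipped at the bottom/right border so
// odd extents still pool (output dim = max(1, floor(d/2))).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int oh = std::max(1, H / 2), ow = std::max(1, W / 2);
  NumericVector y((size_t)oh * ow * C * N);
  IntegerVector idx((size_t)oh * ow * C * N);  // linear index within [H,W] plane
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * oh * ow;
      int* ip = idx.begin() + ((size_t)n * C + c) * oh * ow;
      for (int ox = 0; ox < ow; ++ox) {
        for (int oy = 0; oy < oh; ++oy) {
          const int y0 = 2 * oy, x0 = 2 * ox;
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int dx = 0; dx < 2; ++dx) {
            for (int dy = 0; dy < 2; ++dy) {
              const int yy = y0 + dy, xx = x0 + dx;
              if (yy >= H || xx >= W) continue;
              const double v = xp[yy + (size_t)H * xx];
              if (v > best) { best = v; besti = yy + H * xx; }
            }
          }
          yp[oy + (size_t)oh * ox] = best;
          ip[oy + (size_t)oh * ox] = besti;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane_out = gy.size() / ((size_t)C * N);
  NumericVector gx((size_t)H * W * C * N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gp = gy.begin() + cn * plane_out;
    const int* ip = idx.begin() + cn * plane_out;
    double* xp = gx.begin() + cn * H * W;
    for (size_t p = 0; p < plane_out; ++p) xp[ip[p]] += gp[p];
  }
  gx.attr("dim") = xdim;
  return gx;
}

static inline void bilinear_coeff(int o, int in_size, double scale,
                                  int& i0, int& i1, double& w1) {
  double src = (o + 0.5) * scale - 0.5;
  if (src < 0) src = 0;
  if (src > in_size - 1) src = in_size - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, in_size - 1);
  w1 = src - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, IntegerVector xdim,
                                      int oh, int ow) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const double sy = (double)H / oh, sx = (double)W / ow;
  NumericVector y((size_t)oh * ow * C * N);
  std::vector<int> y0(oh), y1(oh), x0(ow), x1(ow);
  std::vector<double> wy(oh), wx(ow);
  for (int o = 0; o < oh; ++o) bilinear_coeff(o, H, sy, y0[o], y1[o], wy[o]);
  for (int o = 0; o < ow; ++o) bilinear_coeff(o, W, sx, x0[o], x1[o], wx[o]);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * H * W;
    double* yp = y.begin() + cn * oh * ow;
    for (int ox = 0; ox < ow; ++ox) {
      const double* cl = xp + (size_t)H * x0[ox];
      const double* cr = xp + (size_t)H * x1[ox];
      const double wxr = wx[ox], wxl = 1.0 - wxr;
      for (int oy = 0; oy < oh; ++oy) {
        const double wyb = wy[oy], wyt = 1.0 - wyb;
        yp[oy + (size_t)oh * ox] =
          wyt * (wxl * cl[y0[oy]] + wxr * cr[y0[oy]]) +
          wyb * (wxl * cl[y1[oy]] + wxr * cr[y1[oy]]);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gy, IntegerVector ydim,
                                      int H, int W) {
  const int oh = ydim[0], ow = ydim[1], C = ydim[2], N = ydim[3];
  const double sy = (double)H / oh, sx = (double)W / ow;
  NumericVector gx((size_t)H * W * C * N);
  std::vector<int> y0(oh), y1(oh), x0(ow), x1(ow);
  std::vector<double> wy(oh), wx(ow);
  for (int o = 0; o < oh; ++o) bilinear_coeff(o, H, sy, y0[o], y1[o], wy[o]);
  for (int o = 0; o < ow; ++o) bilinear_coeff(o, W, sx, x0[o], x1[o], wx[o]);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gp = gy.begin() + cn * oh * ow;
    double* xp = gx.begin() + cn * H * W;
    for (int ox = 0; ox < ow; ++ox) {
      double* cl = xp + (size_t)H * x0[ox];
      double* cr = xp + (size_t)H * x1[ox];
      const double wxr = wx[ox], wxl = 1.0 - wxr;
      for (int oy = 0; oy < oh; ++oy) {
        const double g = gp[oy + (size_t)oh * ox];
        const double wyb = wy[oy], wyt = 1.0 - wyb;
        cl[y0[oy]] += wyt * wxl * g;
        cr[y0[oy]] += wyt * wxr * g;
        cl[y1[oy]] += wyb * wxl * g;
        cr[y1[oy]] += wyb * wxr * g;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}
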