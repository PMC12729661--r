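// Numerical kernels for the autodiff core: GEMM-based full convolutions,
// direct depthwise convolutions, the selective-scan recurrence, and a
// nearest-boundary-distance helper for HD95.
//
// Array layout convention (matches the R side): images/feature maps are
// numeric arrays with dim = c(H, W, C), column-major, so each channel plane
// is contiguous. Full-conv weights have dim = c(kh, kw, Cin, Cout);
// depthwise weights dim = c(kh, kw, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Build the im2col matrix: K x P with K = kh*kw*Cin (index dh + kh*dw +
// kh*kw*ci, i.e. column-major over (kh, kw, Cin)) and P = Ho*Wo (index
// ho + Ho*wo). Zero padding.
static arma::mat im2col(const double* x, int H, int W, int Cin,
                        int kh, int kw, int stride, int pad, int dil,
                        int Ho, int Wo) {
  const int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat cols(K, P, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* plane = x + (size_t)H * W * ci;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int krow = dh + kh * dw + kh * kw * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dw * dil;
          if (wi < 0 || wi >= W) continue;
          const double* col_in = plane + (size_t)H * wi;
          double* out = cols.memptr() + (size_t)K * (size_t)Ho * wo + krow;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + dh * dil;
            if (hi < 0 || hi >= H) continue;
            out[(size_t)K * ho] = col_in[hi];
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add of a K x P column matrix back onto an (H, W, Cin) grid.
static void col2im(const arma::mat& cols, double* gx, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo) {
  const int K = kh * kw * Cin;
  for (int ci = 0; ci < Cin; ++ci) {
    double* plane = gx + (size_t)H * W * ci;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int krow = dh + kh * dw + kh * kw * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dw * dil;
          if (wi < 0 || wi >= W) continue;
          double* col_out = plane + (size_t)H * wi;
          const double* in = cols.memptr() + (size_t)K * (size_t)Ho * wo + krow;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + dh * dil;
            if (hi < 0 || hi >= H) continue;
            col_out[hi] += in[(size_t)K * ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad, dil);
  const int Wo = out_size(W, kw, stride, pad, dil);
  const int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat cols = im2col(x.begin(), H, W, Cin, kh, kw, stride, pad, dil, Ho, Wo);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((size_t)P * Cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  arma::mat yR(out.begin(), P, Cout, false, true);   // R layout directly
  yR = cols.t() * Wm;
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_bwd_input")]]
NumericVector cpp_conv_bwd_input(NumericVector gy, NumericVector w,
                                 int H, int W, int stride, int pad, int dil) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("conv bwd: channel mismatch");
  const int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat gyR(const_cast<double*>(gy.begin()), P, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gcols = Wm * gyR.t();          // K x P
  NumericVector gx((size_t)H * W * Cin);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  col2im(gcols, gx.begin(), H, W, Cin, kh, kw, stride, pad, dil, Ho, Wo);
  return gx;
}

// [[Rcpp::export(name = ".cpp_conv_bwd_weight")]]
NumericVector cpp_conv_bwd_weight(NumericVector x, NumericVector gy,
                                  int kh, int kw, int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  const int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat cols = im2col(x.begin(), H, W, Cin, kh, kw, stride, pad, dil, Ho, Wo);
  arma::mat gyR(const_cast<double*>(gy.begin()), P, Cout, false, true);
  NumericVector out((size_t)K * Cout);
  out.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  arma::mat gW(out.begin(), K, Cout, false, true);
  gW = cols * gyR;                         // K x Cout, matches weight layout
  return out;
}

// Depthwise convolution: each channel convolved with its own kh x kw kernel.
// [[Rcpp::export(name = ".cpp_dwconv_fwd")]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad, dil);
  const int Wo = out_size(W, kw, stride, pad, dil);
  NumericVector out((size_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = xp + (size_t)H * W * c;
    const double* ker = wp + (size_t)kh * kw * c;
    double* oplane = op + (size_t)Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = wo * stride - pad + dw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = ho * stride - pad + dh * dil;
            if (hi < 0 || hi >= H) continue;
            acc += plane[hi + (size_t)H * wi] * ker[dh + kh * dw];
          }
        }
        oplane[ho + (size_t)Ho * wo] = acc;
      }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_dwconv_bwd_input")]]
NumericVector cpp_dwconv_bwd_input(NumericVector gy, NumericVector w,
                                   int H, int W, int stride, int pad, int dil) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2];
  const int kh = wd[0], kw = wd[1];
  NumericVector gx((size_t)H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  const double* gp = gy.begin(); const double* wp = w.begin();
  double* xp = gx.begin();
  for (int c = 0; c < C; ++c) {
    double* plane = xp + (size_t)H * W * c;
    const double* ker = wp + (size_t)kh * kw * c;
    const double* gplane = gp + (size_t)Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = gplane[ho + (size_t)Ho * wo];
        if (g == 0.0) continue;
        for (int dw = 0; dw < kw; ++dw) {
          const int wi = wo * stride - pad + dw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hi = ho * stride - pad + dh * dil;
            if (hi < 0 || hi >= H) continue;
            plane[hi + (size_t)H * wi] += g * ker[dh + kh * dw];
          }
        }
      }
  }
  return gx;
}

// [[Rcpp::export(name = ".cpp_dwconv_bwd_weight")]]
NumericVector cpp_dwconv_bwd_weight(NumericVector x, NumericVector gy,
                                    int kh, int kw, int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gw((size_t)kh * kw * C);
  gw.attr("dim") = IntegerVector::create(kh, kw, C);
  const double* xp = x.begin(); const double* gp = gy.begin();
  double* wp = gw.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = xp + (size_t)H * W * c;
    const double* gplane = gp + (size_t)Ho * Wo * c;
    double* ker = wp + (size_t)kh * kw * c;
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        double acc = 0.0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + dh * dil;
            if (hi < 0 || hi >= H) continue;
            acc += plane[hi + (size_t)H * wi] * gplane[ho + (size_t)Ho * wo];
          }
        }
        ker[dh + kh * dw] = acc;
      }
  }
  return gw;
}


// Fused input+weight gradient of the full convolution: builds the im2col
// matrix once and reuses it for both products.
// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat cols = im2col(x.begin(), H, W, Cin, kh, kw, stride, pad, dil, Ho, Wo);
  arma::mat gyR(const_cast<double*>(gy.begin()), P, Cout, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gcols = Wm * gyR.t();
  NumericVector gx((size_t)H * W * Cin);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  col2im(gcols, gx.begin(), H, W, Cin, kh, kw, stride, pad, dil, Ho, Wo);
  NumericVector gw((size_t)K * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  arma::mat gW(gw.begin(), K, Cout, false, true);
  gW = cols * gyR;
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// For each point in `a` (n x 2 matrix of row/col indices), the distance to
// the nearest point in `b`, under anisotropic spacing (mm per pixel).
// [[Rcpp::export(name = ".cpp_nn_dist")]]
arma::vec cpp_nn_dist(const arma::mat& a, const arma::mat& b,
                      double sr, double sc) {
  const int n = a.n_rows, m = b.n_rows;
  arma::vec out(n);
  for (int i = 0; i < n; ++i) {
    const double ar = a(i, 0) * sr, ac = a(i, 1) * sc;
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double dr = ar - b(j, 0) * sr, dc = ac - b(j, 1) * sc;
      const double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
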