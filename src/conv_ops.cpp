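// Dense 2-D convolution kernels for the autodiff engine.
// Array convention throughout: images are R arrays [H, W, C, N] (column-major,
// H fastest), kernels are [kh, kw, Cin, Cout].  im2col + GEMM; the column
// matrix has row index ki + kh*(kj + kw*ci) and column index ho + Ho*wo, so a
// flat reshape of the kernel array is directly the GEMM operand.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int stride, int pad, int dil) {
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& col) {
  // col: (kh*kw*C) x (Ho*Wo), pre-allocated
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          double* dst = col.colptr(0) + row; // element (row, ho + Ho*wo)
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            dst[(size_t)(ho + Ho * wo) * col.n_rows] = xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int dil,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_dim(H, kh, stride, pad, dil), Wo = out_dim(W, kw, stride, pad, dil);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, col);
    arma::mat yn(y.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout, false, true);
    yn = col.t() * Wm;
    yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_dim(H, kh, stride, pad, dil), Wo = out_dim(W, kw, stride, pad, dil);
  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = xd;
  NumericVector dw(Rf_allocVector(REALSXP, w.size()));
  std::fill(dw.begin(), dw.end(), 0.0);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col(xn, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, col);
    dWm += col * dyn;
    dbv += arma::sum(dyn, 0);
    if (need_dx) {
      arma::mat dcol = Wm * dyn.t();
      col2im_add(dcol, H, W, C, kh, kw, stride, pad, dil, Ho, Wo,
                 dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, kernel 2x2 stride 2 (the U-Net up-convolution):
// y[2i+a, 2j+b, co] = sum_ci x[i,j,ci] * w[a,b,ci,co] + bias[co]
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("convt2: channel mismatch");
  int Ho = 2 * H, Wo = 2 * W;
  // Wm: (Cin, 4*Cout) with column a + 2*b + 4*co
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int bj = 0; bj < 2; ++bj)
        for (int ai = 0; ai < 2; ++ai)
          Wm(ci, ai + 2 * bj + 4 * co) = w[ai + 2 * (bj + 2 * (ci + (size_t)Cin * co))];
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    arma::mat Yn = Xn * Wm; // (HW, 4*Cout)
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double bias = b[co];
      double* yc = yn + (size_t)co * Ho * Wo;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          size_t src = i + (size_t)H * j;
          yc[(2 * i)     + (size_t)Ho * (2 * j)]     = Yn(src, 0 + 4 * co) + bias;
          yc[(2 * i + 1) + (size_t)Ho * (2 * j)]     = Yn(src, 1 + 4 * co) + bias;
          yc[(2 * i)     + (size_t)Ho * (2 * j + 1)] = Yn(src, 2 + 4 * co) + bias;
          yc[(2 * i + 1) + (size_t)Ho * (2 * j + 1)] = Yn(src, 3 + 4 * co) + bias;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cin = wd[2], Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int bj = 0; bj < 2; ++bj)
        for (int ai = 0; ai < 2; ++ai)
          Wm(ci, ai + 2 * bj + 4 * co) = w[ai + 2 * (bj + 2 * (ci + (size_t)Cin * co))];
  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = xd;
  NumericVector dw(Rf_allocVector(REALSXP, w.size()));
  std::fill(dw.begin(), dw.end(), 0.0);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(Cin, 4 * Cout, arma::fill::zeros);
  arma::mat dYn((size_t)H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)co * Ho * Wo;
      double s = 0.0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          size_t dst = i + (size_t)H * j;
          double g00 = dyc[(2 * i)     + (size_t)Ho * (2 * j)];
          double g10 = dyc[(2 * i + 1) + (size_t)Ho * (2 * j)];
          double g01 = dyc[(2 * i)     + (size_t)Ho * (2 * j + 1)];
          double g11 = dyc[(2 * i + 1) + (size_t)Ho * (2 * j + 1)];
          dYn(dst, 0 + 4 * co) = g00; dYn(dst, 1 + 4 * co) = g10;
          dYn(dst, 2 + 4 * co) = g01; dYn(dst, 3 + 4 * co) = g11;
          s += g00 + g10 + g01 + g11;
        }
      db[co] += s;
    }
    arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                 (size_t)H * W, C, false, true);
    arma::mat dXn(dx.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    dXn += dYn * Wm.t();
    dWm += Xn.t() * dYn;
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int bj = 0; bj < 2; ++bj)
        for (int ai = 0; ai < 2; ++ai)
          dw[ai + 2 * (bj + 2 * (ci + (size_t)Cin * co))] = dWm(ci, ai + 2 * bj + 4 * co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; returns pooled values and flat argmax indices
// (0-based into the H*W plane of each channel/sample) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * N));
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      double* yc = y.begin() + (size_t)(n * C + c) * Ho * Wo;
      int* ic = idx.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int i0 = 2 * ho, j0 = 2 * wo;
          int best = i0 + H * j0;
          double bv = xc[best];
          int cand[3] = { i0 + 1 + H * j0, i0 + H * (j0 + 1), i0 + 1 + H * (j0 + 1) };
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
          yc[ho + (size_t)Ho * wo] = bv;
          ic[ho + (size_t)Ho * wo] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)(n * C + c) * H * W;
      const double* dyc = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      const int* ic = idx.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k) dxc[ic[k]] += dyc[k];
    }
  return dx;
}
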