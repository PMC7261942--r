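// Layer primitives for the compact 2D U-Net: same-padded k x k convolution
// (im2col + BLAS matmul), 2x2 max-pooling, and 2x2 stride-2 transpose
// convolution, each with its analytic backward pass. Feature maps are R
// arrays [H, W, C, N] (column-major); weights are [kh, kw, Cin, Cout], so a
// weight array reinterpreted as a (kh*kw*Cin) x Cout matrix matches the
// im2col column ordering (kh fastest, then kw, then input channel).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& M) {
  // M: (H*W) x (k*k*C), output pixel (h + H*w) in rows
  M.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * (kw + k * ci);
        double* mcol = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          int sw = w + kw - pad;
          if (sw < 0 || sw >= W) continue;
          const double* xsrc = xc + (size_t)H * sw;
          double* mdst = mcol + (size_t)H * w;
          int h0 = std::max(0, pad - kh);
          int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h) mdst[h] = xsrc[h + kh - pad];
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, int H, int W, int C, int k, int pad,
                       double* gx) {
  for (int ci = 0; ci < C; ++ci) {
    double* gc = gx + (size_t)H * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * (kw + k * ci);
        const double* mcol = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          int sw = w + kw - pad;
          if (sw < 0 || sw >= W) continue;
          double* gdst = gc + (size_t)H * sw;
          const double* msrc = mcol + (size_t)H * w;
          int h0 = std::max(0, pad - kh);
          int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h) gdst[h + kh - pad] += msrc[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(const NumericVector& x, const NumericVector& w,
                         const NumericVector& bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int pad = (k - 1) / 2;
  NumericVector y(R_xlen_t(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat M(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, M);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n, H * W, Cout,
                false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(const NumericVector& x, const NumericVector& w,
                const NumericVector& gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int pad = (k - 1) / 2;
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw(R_xlen_t(k) * k * C * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat Gw(gw.begin(), k * k * C, Cout, false, true);
  arma::vec Gb(gb.begin(), Cout, false, true);
  arma::mat M(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)H * W * Cout * n,
                 H * W, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, M);
    Gw += M.t() * Gy;
    Gb += arma::sum(Gy, 0).t();
    arma::mat Gcols = Gy * Wm.t();
    col2im_add(Gcols, H, W, C, k, pad, gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export]]
List maxpool2_fwd(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(R_xlen_t(Ho) * Wo * C * N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t yb = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int best = 2 * ho + H * (2 * wo);
          double bv = xs[best];
          const int cand[3] = {2 * ho + 1 + H * (2 * wo),
                               2 * ho + H * (2 * wo + 1),
                               2 * ho + 1 + H * (2 * wo + 1)};
          for (int t = 0; t < 3; ++t) {
            if (xs[cand[t]] > bv) { bv = xs[cand[t]]; best = cand[t]; }
          }
          y[yb + ho + Ho * wo] = bv;
          arg[yb + ho + Ho * wo] = best;
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(const NumericVector& gy, const IntegerVector& arg,
                           int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t yb = (size_t)Ho * Wo * (c + (size_t)C * n);
      size_t xb = (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) {
        gx[xb + arg[yb + i]] += gy[yb + i];
      }
    }
  }
  return gx;
}

static arma::mat upconv_wmat(const NumericVector& w, int Cin, int Cout) {
  // w: [2, 2, Cin, Cout] -> Wm(ci, dh + 2*dw + 4*co)
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dw = 0; dw < 2; ++dw) {
        for (int dh = 0; dh < 2; ++dh) {
          Wm(ci, dh + 2 * dw + 4 * co) = w[dh + 2 * (dw + 2 * (ci + Cin * co))];
        }
      }
    }
  }
  return Wm;
}

// [[Rcpp::export]]
NumericVector upconv2_fwd(const NumericVector& x, const NumericVector& w,
                          const NumericVector& bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(R_xlen_t(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm = upconv_wmat(w, Cin, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                H * W, Cin, false, true);
    arma::mat Y4 = X * Wm;  // (H*W) x (4*Cout)
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      for (int dw = 0; dw < 2; ++dw) {
        for (int dh = 0; dh < 2; ++dh) {
          const double* src = Y4.colptr(dh + 2 * dw + 4 * co);
          for (int w2 = 0; w2 < W; ++w2) {
            for (int h2 = 0; h2 < H; ++h2) {
              yn[(2 * h2 + dh) + (size_t)Ho * ((2 * w2 + dw) + (size_t)Wo * co)] =
                src[h2 + H * w2] + bias[co];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv2_bwd(const NumericVector& x, const NumericVector& w,
                 const NumericVector& gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(R_xlen_t(H) * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gw(R_xlen_t(2) * 2 * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm = upconv_wmat(w, Cin, Cout);
  arma::mat Gwm(Cin, 4 * Cout, arma::fill::zeros);
  arma::mat G4(H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double acc = 0.0;
      for (int dw = 0; dw < 2; ++dw) {
        for (int dh = 0; dh < 2; ++dh) {
          double* dst = G4.colptr(dh + 2 * dw + 4 * co);
          for (int w2 = 0; w2 < W; ++w2) {
            for (int h2 = 0; h2 < H; ++h2) {
              double g = gyn[(2 * h2 + dh) +
                             (size_t)Ho * ((2 * w2 + dw) + (size_t)Wo * co)];
              dst[h2 + H * w2] = g;
              acc += g;
            }
          }
        }
      }
      gb[co] += acc;
    }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                H * W, Cin, false, true);
    arma::mat Gx(gx.begin() + (size_t)H * W * Cin * n, H * W, Cin,
                 false, true);
    Gx = G4 * Wm.t();
    Gwm += X.t() * G4;
  }
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dw = 0; dw < 2; ++dw) {
        for (int dh = 0; dh < 2; ++dh) {
          gw[dh + 2 * (dw + 2 * (ci + Cin * co))] =
            Gwm(ci, dh + 2 * dw + 4 * co);
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}
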