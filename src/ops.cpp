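// Low-level tensor kernels for the segmentation engine.
//
// All activation tensors are dense double arrays with dim (H, W, C, N),
// R column-major order. Convolution weights have dim (kh, kw, Cin, Cout);
// depthwise weights (kh, kw, C); transposed-conv weights (2, 2, Cin, Cout).
// Stride is always 1 for plain convolution (downsampling is done by pooling),
// which keeps the im2col bookkeeping simple and the gradients exact.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int d[4], const char* what) {
  SEXP a = x.attr("dim");
  if (Rf_isNull(a)) stop("%s must have a dim attribute", what);
  IntegerVector dm(a);
  if (dm.size() != 4 && dm.size() != 3) stop("%s must be a 3d or 4d array", what);
  d[0] = dm[0]; d[1] = dm[1]; d[2] = dm.size() > 2 ? dm[2] : 1;
  d[3] = dm.size() > 3 ? dm[3] : 1;
}

// Fill the im2col matrix (K x Ho*Wo) for sample xn.
static void im2col(const double* xn, int H, int W, int Cin,
                   int kh, int kw, int padh, int padw,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int ci = 0; ci < Cin; ci++) {
    for (int kwi = 0; kwi < kw; kwi++) {
      for (int khi = 0; khi < kh; khi++) {
        const int r = khi + kh * (kwi + kw * ci);
        for (int wo = 0; wo < Wo; wo++) {
          const int wi = wo - padw + kwi;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xn + (size_t)H * (wi + (size_t)W * ci);
          double* crow = col.colptr(0);
          for (int ho = 0; ho < Ho; ho++) {
            const int hi = ho - padh + khi;
            if (hi < 0 || hi >= H) continue;
            col(r, ho + (size_t)Ho * wo) = xcol[hi];
          }
          (void)crow;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int padh, int padw) {
  int xd[4], wd[4];
  dims4(x, xd, "x"); dims4(w, wd, "w");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = H + 2 * padh - kh + 1;
  const int Wo = W + 2 * padw - kw + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv2d: kernel larger than padded input");
  const int K = kh * kw * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, (size_t)Ho * Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; n++) {
    im2col(xp + (size_t)H * W * C * n, H, W, Cin, kh, kw, padh, padw, Ho, Wo, col);
    arma::mat out = col.t() * Wm;             // (Ho*Wo, Cout)
    double* yn = yp + (size_t)Ho * Wo * Cout * n;
    std::memcpy(yn, out.memptr(), sizeof(double) * (size_t)Ho * Wo * Cout);
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int co = 0; co < Cout; co++) {
        const double bb = b[co];
        double* yc = yn + (size_t)Ho * Wo * co;
        for (size_t i = 0; i < (size_t)Ho * Wo; i++) yc[i] += bb;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int padh, int padw, bool has_bias) {
  int xd[4], wd[4], yd[4];
  dims4(x, xd, "x"); dims4(w, wd, "w"); dims4(dy, yd, "dy");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector dx(x.size());  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat col(K, (size_t)Ho * Wo);

  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; n++) {
    im2col(xp + (size_t)H * W * C * n, H, W, Cin, kh, kw, padh, padw, Ho, Wo, col);
    arma::mat G(const_cast<double*>(dyp) + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    dWm += col * G;
    if (has_bias)
      for (int co = 0; co < Cout; co++) db[co] += arma::accu(G.col(co));
    arma::mat dcol = Wm * G.t();              // (K, Ho*Wo)
    double* dxn = dxp + (size_t)H * W * C * n;
    for (int ci = 0; ci < Cin; ci++) {
      for (int kwi = 0; kwi < kw; kwi++) {
        for (int khi = 0; khi < kh; khi++) {
          const int r = khi + kh * (kwi + kw * ci);
          for (int wo = 0; wo < Wo; wo++) {
            const int wi = wo - padw + kwi;
            if (wi < 0 || wi >= W) continue;
            double* dxcol = dxn + (size_t)H * (wi + (size_t)W * ci);
            for (int ho = 0; ho < Ho; ho++) {
              const int hi = ho - padh + khi;
              if (hi < 0 || hi >= H) continue;
              dxcol[hi] += dcol(r, ho + (size_t)Ho * wo);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise convolution: one spatial kernel per channel, channels preserved.
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int padh, int padw) {
  int xd[4], wd[4];
  dims4(x, xd, "x"); dims4(w, wd, "w");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv: input has %d channels, weights expect %d", C, wd[2]);
  const int Ho = H + 2 * padh - kh + 1;
  const int Wo = W + 2 * padw - kw + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* yc = yp + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double b = bias.isNotNull() ? NumericVector(bias)[c] : 0.0;
      for (int wo = 0; wo < Wo; wo++) {
        for (int ho = 0; ho < Ho; ho++) {
          double acc = b;
          for (int kwi = 0; kwi < kw; kwi++) {
            const int wi = wo - padw + kwi;
            if (wi < 0 || wi >= W) continue;
            for (int khi = 0; khi < kh; khi++) {
              const int hi = ho - padh + khi;
              if (hi < 0 || hi >= H) continue;
              acc += wc[khi + kh * kwi] * xc[hi + (size_t)H * wi];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int padh, int padw, bool has_bias) {
  int xd[4], wd[4], yd[4];
  dims4(x, xd, "x"); dims4(w, wd, "w"); dims4(dy, yd, "dy");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size()); dw.attr("dim") = w.attr("dim");
  NumericVector db(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* gyc = dyp + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      for (int wo = 0; wo < Wo; wo++) {
        for (int ho = 0; ho < Ho; ho++) {
          const double g = gyc[ho + (size_t)Ho * wo];
          if (has_bias) db[c] += g;
          for (int kwi = 0; kwi < kw; kwi++) {
            const int wi = wo - padw + kwi;
            if (wi < 0 || wi >= W) continue;
            for (int khi = 0; khi < kh; khi++) {
              const int hi = ho - padh + khi;
              if (hi < 0 || hi >= H) continue;
              dwc[khi + kh * kwi] += g * xc[hi + (size_t)H * wi];
              dxc[hi + (size_t)H * wi] += g * wc[khi + kh * kwi];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling, general kernel/stride/padding; idx stores the 0-based linear
// index of the winning input element so the backward pass is a scatter.
// Ties go to the first element in scan order (deterministic).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  int xd[4];
  dims4(x, xd, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("maxpool: pooling window larger than input");
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      const size_t yoff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; wo++) {
        for (int ho = 0; ho < Ho; ho++) {
          double best = R_NegInf; size_t besti = 0; bool found = false;
          for (int kwi = 0; kwi < k; kwi++) {
            const int wi = wo * stride - pad + kwi;
            if (wi < 0 || wi >= W) continue;
            for (int khi = 0; khi < k; khi++) {
              const int hi = ho * stride - pad + khi;
              if (hi < 0 || hi >= H) continue;
              const size_t xi = xoff + hi + (size_t)H * wi;
              if (!found || xp[xi] > best) { best = xp[xi]; besti = xi; found = true; }
            }
          }
          if (!found) stop("maxpool: empty window");
          y[yoff + ho + (size_t)Ho * wo] = best;
          idx[yoff + ho + (size_t)Ho * wo] = (int)besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  R_xlen_t len = 1;
  for (int i = 0; i < xdim.size(); i++) len *= xdim[i];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); i++) dx[idx[i]] += dy[i];
  return dx;
}

// Transposed convolution, kernel 2, stride 2: exact x2 learnable upsampling.
// [[Rcpp::export]]
NumericVector upconv2_fwd_cpp(NumericVector x, NumericVector w,
                              Nullable<NumericVector> bias) {
  int xd[4], wd[4];
  dims4(x, xd, "x"); dims4(w, wd, "w");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  if (wd[0] != 2 || wd[1] != 2) stop("upconv2: kernel must be 2x2");
  if (wd[2] != Cin) stop("upconv2: channel mismatch");
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  arma::mat Wab(Cin, Cout);
  for (int n = 0; n < N; n++) {
    arma::mat X(const_cast<double*>(xp) + (size_t)H * W * Cin * n,
                (size_t)H * W, Cin, false, true);
    double* yn = yp + (size_t)Ho * Wo * Cout * n;
    for (int a = 0; a < 2; a++) {
      for (int b2 = 0; b2 < 2; b2++) {
        for (int ci = 0; ci < Cin; ci++)
          for (int co = 0; co < Cout; co++)
            Wab(ci, co) = w[a + 2 * (b2 + 2 * (ci + (size_t)Cin * co))];
        arma::mat out = X * Wab;              // (H*W, Cout)
        for (int co = 0; co < Cout; co++) {
          const double bb = bias.isNotNull() ? NumericVector(bias)[co] : 0.0;
          for (int wi = 0; wi < W; wi++) {
            for (int hi = 0; hi < H; hi++) {
              yn[(2 * hi + a) + (size_t)Ho * ((2 * wi + b2) + (size_t)Wo * co)] =
                out(hi + (size_t)H * wi, co) + bb;
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv2_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                     bool has_bias) {
  int xd[4], wd[4];
  dims4(x, xd, "x"); dims4(w, wd, "w");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size()); dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  arma::mat Wab(Cin, Cout), Gab((size_t)H * W, Cout);
  for (int n = 0; n < N; n++) {
    arma::mat X(const_cast<double*>(xp) + (size_t)H * W * Cin * n,
                (size_t)H * W, Cin, false, true);
    arma::mat dX(dx.begin() + (size_t)H * W * Cin * n,
                 (size_t)H * W, Cin, false, true);
    const double* gyn = dyp + (size_t)Ho * Wo * Cout * n;
    for (int a = 0; a < 2; a++) {
      for (int b2 = 0; b2 < 2; b2++) {
        for (int ci = 0; ci < Cin; ci++)
          for (int co = 0; co < Cout; co++)
            Wab(ci, co) = w[a + 2 * (b2 + 2 * (ci + (size_t)Cin * co))];
        for (int co = 0; co < Cout; co++)
          for (int wi = 0; wi < W; wi++)
            for (int hi = 0; hi < H; hi++)
              Gab(hi + (size_t)H * wi, co) =
                gyn[(2 * hi + a) + (size_t)Ho * ((2 * wi + b2) + (size_t)Wo * co)];
        arma::mat dWab = X.t() * Gab;         // (Cin, Cout)
        for (int ci = 0; ci < Cin; ci++)
          for (int co = 0; co < Cout; co++)
            dw[a + 2 * (b2 + 2 * (ci + (size_t)Cin * co))] += dWab(ci, co);
        dX += Gab * Wab.t();
        if (has_bias)
          for (int co = 0; co < Cout; co++) db[co] += arma::accu(Gab.col(co));
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear resize (align_corners = FALSE, edge-clamped), any target size.
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector x, int Ho, int Wo) {
  int xd[4];
  dims4(x, xd, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < Wo; wo++) {
    double sx = (wo + 0.5) * sw - 0.5;
    if (sx < 0) sx = 0; if (sx > W - 1) sx = W - 1;
    const int x0 = (int)sx, x1 = x0 < W - 1 ? x0 + 1 : x0;
    const double fx = sx - x0;
    for (int ho = 0; ho < Ho; ho++) {
      double sy = (ho + 0.5) * sh - 0.5;
      if (sy < 0) sy = 0; if (sy > H - 1) sy = H - 1;
      const int y0 = (int)sy, y1 = y0 < H - 1 ? y0 + 1 : y0;
      const double fy = sy - y0;
      for (int n = 0; n < N; n++) {
        for (int c = 0; c < C; c++) {
          const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
          const double v =
            (1 - fy) * (1 - fx) * xc[y0 + (size_t)H * x0] +
            (1 - fy) * fx       * xc[y0 + (size_t)H * x1] +
            fy       * (1 - fx) * xc[y1 + (size_t)H * x0] +
            fy       * fx       * xc[y1 + (size_t)H * x1];
          yp[ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n))] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bwd_cpp(NumericVector dy, int H, int W) {
  int yd[4];
  dims4(dy, yd, "dy");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* gp = dy.begin();
  double* dp = dx.begin();
  for (int wo = 0; wo < Wo; wo++) {
    double sx = (wo + 0.5) * sw - 0.5;
    if (sx < 0) sx = 0; if (sx > W - 1) sx = W - 1;
    const int x0 = (int)sx, x1 = x0 < W - 1 ? x0 + 1 : x0;
    const double fx = sx - x0;
    for (int ho = 0; ho < Ho; ho++) {
      double sy = (ho + 0.5) * sh - 0.5;
      if (sy < 0) sy = 0; if (sy > H - 1) sy = H - 1;
      const int y0 = (int)sy, y1 = y0 < H - 1 ? y0 + 1 : y0;
      const double fy = sy - y0;
      for (int n = 0; n < N; n++) {
        for (int c = 0; c < C; c++) {
          const double g =
            gp[ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n))];
          double* dc = dp + (size_t)H * W * (c + (size_t)C * n);
          dc[y0 + (size_t)H * x0] += (1 - fy) * (1 - fx) * g;
          dc[y0 + (size_t)H * x1] += (1 - fy) * fx       * g;
          dc[y1 + (size_t)H * x0] += fy       * (1 - fx) * g;
          dc[y1 + (size_t)H * x1] += fy       * fx       * g;
        }
      }
    }
  }
  return dx;
}
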