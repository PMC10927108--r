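// Low-level tensor primitives for the network code: 2-D convolution,
// transposed convolution, 2x2 max-pooling and bilinear x2 upsampling,
// all single-image (H x W x C arrays, column-major as in R).
//
// Convolutions are im2col + GEMM. Weight arrays have dim (kh, kw, Cin, Cout);
// transposed convolutions store the weights of the "virtual" forward
// convolution, i.e. dim (kh, kw, Cout_t, Cin_t), so that their forward pass
// is the data-gradient of a strided convolution and vice versa.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::List;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// K has one column per output pixel (ho fastest), one row per (ki, kj, c).
static void im2col(const cube& x, int kh, int kw, int stride, int pad,
                   int Ho, int Wo, mat& K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  K.zeros(kh * kw * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + kj - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride + ki - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            K(row, ho + Ho * wo) = xc(hsrc, wsrc);
          }
        }
      }
    }
  }
}

// Scatter-add inverse of im2col.
static void col2im(const mat& K, int kh, int kw, int stride, int pad,
                   int Ho, int Wo, cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  x.zeros();
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + kj - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride + ki - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            xc(hsrc, wsrc) += K(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

static cube as_cube(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  return cube(const_cast<double*>(a.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector wrap_cube(const mat& Yt, int H, int W, int C) {
  // Yt is (H*W) x C column-major, which is exactly the memory layout of an
  // (H, W, C) array.
  NumericVector out(Yt.begin(), Yt.end());
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  cube xc = as_cube(x);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if ((int)xc.n_slices != Cin) Rcpp::stop("conv2d: channel mismatch");
  const int Ho = out_dim(xc.n_rows, kh, stride, pad);
  const int Wo = out_dim(xc.n_cols, kw, stride, pad);
  mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  mat K;
  im2col(xc, kh, kw, stride, pad, Ho, Wo, K);
  mat Yt = K.t() * Wm;                       // (Ho*Wo) x Cout
  for (int o = 0; o < Cout; ++o) Yt.col(o) += b[o];
  return wrap_cube(Yt, Ho, Wo, Cout);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  cube xc = as_cube(x);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  IntegerVector dyd = dy.attr("dim");
  const int Ho = dyd[0], Wo = dyd[1];
  mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  mat dYm(const_cast<double*>(dy.begin()), Ho * Wo, Cout, false, true);
  mat K;
  im2col(xc, kh, kw, stride, pad, Ho, Wo, K);
  mat dW = K * dYm;                          // (kh*kw*Cin) x Cout
  vec db = sum(dYm, 0).t();
  mat dK = Wm * dYm.t();                     // (kh*kw*Cin) x (Ho*Wo)
  cube dx(xc.n_rows, xc.n_cols, Cin);
  col2im(dK, kh, kw, stride, pad, Ho, Wo, dx);
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wd;
  NumericVector dxout(dx.begin(), dx.end());
  dxout.attr("dim") = IntegerVector::create((int)xc.n_rows, (int)xc.n_cols, Cin);
  return List::create(Rcpp::Named("dx") = dxout,
                      Rcpp::Named("dW") = dWout,
                      Rcpp::Named("db") = NumericVector(db.begin(), db.end()));
}

// Transposed convolution forward: x (h, w, Cin_t) -> y (Ho, Wo, Cout_t),
// weights dim (kh, kw, Cout_t, Cin_t). Ho, Wo given explicitly (they encode
// the output padding).
// [[Rcpp::export]]
NumericVector cpp_convt2d_fw(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int Ho, int Wo) {
  cube xc = as_cube(x);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[2], Cin = wd[3];
  if ((int)xc.n_slices != Cin) Rcpp::stop("convt2d: channel mismatch");
  const int h = xc.n_rows, ww = xc.n_cols;
  if (out_dim(Ho, kh, stride, pad) != h || out_dim(Wo, kw, stride, pad) != ww)
    Rcpp::stop("convt2d: inconsistent output size");
  mat Wm(const_cast<double*>(w.begin()), kh * kw * Cout, Cin, false, true);
  mat xm(const_cast<double*>(x.begin()), h * ww, Cin, false, true);
  mat dK = Wm * xm.t();                      // (kh*kw*Cout) x (h*w)
  cube y(Ho, Wo, Cout);
  col2im(dK, kh, kw, stride, pad, h, ww, y);
  for (int o = 0; o < Cout; ++o) y.slice(o) += b[o];
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_convt2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  cube xc = as_cube(x);
  cube dyc = as_cube(dy);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[2], Cin = wd[3];
  const int h = xc.n_rows, ww = xc.n_cols;
  mat Wm(const_cast<double*>(w.begin()), kh * kw * Cout, Cin, false, true);
  mat xm(const_cast<double*>(x.begin()), h * ww, Cin, false, true);
  mat K;
  im2col(dyc, kh, kw, stride, pad, h, ww, K);  // (kh*kw*Cout) x (h*w)
  mat dxm = K.t() * Wm;                        // (h*w) x Cin
  mat dW = K * xm;                             // (kh*kw*Cout) x Cin
  vec db(Cout);
  for (int o = 0; o < Cout; ++o) db[o] = accu(dyc.slice(o));
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wd;
  NumericVector dxout = wrap_cube(dxm, h, ww, Cin);
  return List::create(Rcpp::Named("dx") = dxout,
                      Rcpp::Named("dW") = dWout,
                      Rcpp::Named("db") = NumericVector(db.begin(), db.end()));
}

// 2x2 max-pool, stride 2, floor division of odd dims.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);  // linear index into x of each max
  int n = 0;
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -datum::inf;
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * ho + di, j = 2 * wo + dj;
            const double v = xc(i, j, c);
            if (v > best) { best = v; bi = i + H * (j + W * c); }
          }
        }
        y(ho, wo, c) = best;
        idx[n++] = bi;
      }
    }
  }
  // idx fill order (ho fastest, then wo, then c) matches column-major layout
  NumericVector yout(y.begin(), y.end());
  yout.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(Rcpp::Named("y") = yout, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector dy, IntegerVector idx,
                              IntegerVector dimx) {
  NumericVector dx(dimx[0] * dimx[1] * dimx[2]);
  for (int n = 0; n < dy.size(); ++n) dx[idx[n]] += dy[n];
  dx.attr("dim") = dimx;
  return dx;
}

// Bilinear x2 upsampling (half-pixel centers, edges clamped).
static void up2_weights(int i, int n, int& s0, int& s1, double& w0, double& w1) {
  const double src = (i + 0.5) / 2.0 - 0.5;
  s0 = (int)std::floor(src);
  s1 = s0 + 1;
  w1 = src - s0;
  w0 = 1.0 - w1;
  if (s0 < 0) { s0 = 0; }
  if (s1 > n - 1) { s1 = n - 1; }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < 2 * W; ++j) {
      int js0, js1; double jw0, jw1;
      up2_weights(j, W, js0, js1, jw0, jw1);
      for (int i = 0; i < 2 * H; ++i) {
        int is0, is1; double iw0, iw1;
        up2_weights(i, H, is0, is1, iw0, iw1);
        y(i, j, c) = iw0 * jw0 * xc(is0, js0, c) + iw1 * jw0 * xc(is1, js0, c)
                   + iw0 * jw1 * xc(is0, js1, c) + iw1 * jw1 * xc(is1, js1, c);
      }
    }
  }
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy, IntegerVector dimx) {
  const int H = dimx[0], W = dimx[1], C = dimx[2];
  cube dyc = as_cube(dy);
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < 2 * W; ++j) {
      int js0, js1; double jw0, jw1;
      up2_weights(j, W, js0, js1, jw0, jw1);
      for (int i = 0; i < 2 * H; ++i) {
        int is0, is1; double iw0, iw1;
        up2_weights(i, H, is0, is1, iw0, iw1);
        const double g = dyc(i, j, c);
        dx(is0, js0, c) += iw0 * jw0 * g;
        dx(is1, js0, c) += iw1 * jw0 * g;
        dx(is0, js1, c) += iw0 * jw1 * g;
        dx(is1, js1, c) += iw1 * jw1 * g;
      }
    }
  }
  NumericVector out(dx.begin(), dx.end());
  out.attr("dim") = dimx;
  return out;
}
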