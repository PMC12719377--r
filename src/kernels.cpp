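// Low-level numerical kernels for 2D convolutional layers and surface
// distances.  All image batches use the R array layout (H, W, C, N),
// column-major; weights are (k, k, Cin, Cout).
//
// im2col matrices are laid out (H*W) x (k*k*C) so that the inner loops read
// and write contiguous memory and the GEMM result (H*W x Cout) aliases the
// output array directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// fill M (HW x kkC) from one sample; column (ki, kj, c)
static inline void im2col(const double *x, int H, int W, int C, int k,
                          int pad, arma::mat &M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double *dst = M.colptr(ki + k * (kj + k * c));
        for (int w = 0; w < W; ++w) {
          int ww = w + kj - pad;
          if (ww < 0 || ww >= W) continue;
          const double *src = xc + (size_t)H * ww;
          double *d = dst + (size_t)H * w;
          int h0 = std::max(0, pad - ki), h1 = std::min(H, H + pad - ki);
          for (int h = h0; h < h1; ++h) d[h] = src[h + ki - pad];
        }
      }
    }
  }
}

// scatter-add dM (HW x kkC) back into one sample's gradient
static inline void col2im_add(double *dx, const arma::mat &dM, int H, int W,
                              int C, int k, int pad) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double *src = dM.colptr(ki + k * (kj + k * c));
        for (int w = 0; w < W; ++w) {
          int ww = w + kj - pad;
          if (ww < 0 || ww >= W) continue;
          double *d = xc + (size_t)H * ww;
          const double *s = src + (size_t)H * w;
          int h0 = std::max(0, pad - ki), h1 = std::min(H, H + pad - ki);
          for (int h = h0; h < h1; ++h) d[h + ki - pad] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2dForward(NumericVector x, NumericVector w, NumericVector b,
                            int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("conv2dForward: channel mismatch");
  const arma::mat Wm(w.begin(), k * k * Cin, Cout, false);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M(H * W, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, M);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n, H * W, Cout, false,
                true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2dBackward(NumericVector x, NumericVector w, NumericVector dy,
                    int pad) {
  IntegerVector dxd = x.attr("dim"), dwd = w.attr("dim");
  int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  int k = dwd[0], Cout = dwd[3];
  const arma::mat Wm(w.begin(), k * k * C, Cout, false);
  NumericVector dxv((size_t)H * W * C * N), dwv(w.size()), dbv(Cout);
  dxv.attr("dim") = x.attr("dim");
  dwv.attr("dim") = w.attr("dim");
  arma::mat dWm(dwv.begin(), k * k * C, Cout, false, true);
  arma::rowvec db(dbv.begin(), Cout, false, true);
  arma::mat M(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, M);
    const arma::mat dY(dy.begin() + (size_t)H * W * Cout * n, H * W, Cout,
                       false);
    dWm += M.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();  // HW x kkC
    col2im_add(dxv.begin() + (size_t)H * W * C * n, dM, H, W, C, k, pad);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// extract the (C x Cout) weight slice of a 2x2 transposed-conv kernel at
// offset (di, dj); w layout (2, 2, Cin, Cout)
static inline arma::mat wSub(const double *w, int C, int Cout, int di,
                             int dj) {
  arma::mat S(C, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      S(c, co) = w[di + 2 * (dj + 2 * (c + (size_t)C * co))];
  return S;
}

// Transposed convolution, kernel 2, stride 2: output (2H, 2W).
// [[Rcpp::export(name = ".convT2dForward")]]
NumericVector convT2dForward(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector dxd = x.attr("dim"), dwd = w.attr("dim");
  int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  int Cout = dwd[3];
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * Cout * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  for (int n = 0; n < N; ++n) {
    const arma::mat X(x.begin() + (size_t)H * W * C * n, H * W, C, false);
    double *yp = y.begin() + (size_t)H2 * W2 * Cout * n;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::mat Y = X * wSub(w.begin(), C, Cout, di, dj);  // HW x Cout
        for (int co = 0; co < Cout; ++co) {
          const double *yc = Y.colptr(co);
          double *out = yp + (size_t)H2 * W2 * co;
          double bc = b[co];
          for (int ww = 0; ww < W; ++ww) {
            double *o = out + (size_t)H2 * (2 * ww + dj) + di;
            const double *s = yc + (size_t)H * ww;
            for (int hh = 0; hh < H; ++hh) o[2 * hh] = s[hh] + bc;
          }
        }
      }
  }
  return y;
}

// [[Rcpp::export(name = ".convT2dBackward")]]
List convT2dBackward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dxd = x.attr("dim"), dwd = w.attr("dim");
  int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  int Cout = dwd[3];
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector dxv(x.size()), dwv(w.size()), dbv(Cout);
  dxv.attr("dim") = x.attr("dim");
  dwv.attr("dim") = w.attr("dim");
  arma::mat dY(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const arma::mat X(x.begin() + (size_t)H * W * C * n, H * W, C, false);
    arma::mat dX(dxv.begin() + (size_t)H * W * C * n, H * W, C, false, true);
    const double *dyp = dy.begin() + (size_t)H2 * W2 * Cout * n;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        for (int co = 0; co < Cout; ++co) {
          double *d = dY.colptr(co);
          const double *src = dyp + (size_t)H2 * W2 * co;
          for (int ww = 0; ww < W; ++ww) {
            const double *s = src + (size_t)H2 * (2 * ww + dj) + di;
            double *dcol = d + (size_t)H * ww;
            for (int hh = 0; hh < H; ++hh) dcol[hh] = s[2 * hh];
          }
          dbv[co] += arma::accu(dY.col(co));
        }
        arma::mat S = wSub(w.begin(), C, Cout, di, dj);
        dX += dY * S.t();
        arma::mat dS = X.t() * dY;  // C x Cout
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < C; ++c)
            dwv[di + 2 * (dj + 2 * (c + (size_t)C * co))] += dS(c, co);
      }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling (H, W even); returns pooled values and flat argmax indices
// (1-based into the input array) for the backward pass.
// [[Rcpp::export(name = ".maxPoolForward")]]
List maxPoolForward(NumericVector x) {
  IntegerVector dxd = x.attr("dim");
  int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  if (H % 2 || W % 2) stop("maxPoolForward: H and W must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      const double *xc = x.begin() + base;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++q) {
          double best = -INFINITY;
          size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t p = (2 * ho + di) + (size_t)H * (2 * wo + dj);
              if (xc[p] > best) {
                best = xc[p];
                bi = p;
              }
            }
          y[q] = best;
          idx[q] = (int)(base + bi) + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxPoolBackward")]]
NumericVector maxPoolBackward(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// leaky ReLU, elementwise
// [[Rcpp::export(name = ".lreluForward")]]
NumericVector lreluForward(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export(name = ".lreluBackward")]]
NumericVector lreluBackward(NumericVector x, NumericVector dy, double slope) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    dx[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dx;
}

// instance normalization over the spatial plane of each (channel, sample)
// [[Rcpp::export(name = ".inormForward")]]
List inormForward(NumericVector x, double eps) {
  IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int groups = d[2] * d[3];
  NumericVector y(x.size()), sig(groups);
  y.attr("dim") = x.attr("dim");
  for (int g = 0; g < groups; ++g) {
    const double *xs = x.begin() + hw * g;
    double m = 0, m2 = 0;
    for (size_t i = 0; i < hw; ++i) { m += xs[i]; m2 += xs[i] * xs[i]; }
    m /= hw;
    double v = m2 / hw - m * m;
    double s = std::sqrt((v > 0 ? v : 0) + eps);
    sig[g] = s;
    double *ys = y.begin() + hw * g;
    for (size_t i = 0; i < hw; ++i) ys[i] = (xs[i] - m) / s;
  }
  return List::create(_["y"] = y, _["sig"] = sig);
}

// [[Rcpp::export(name = ".inormBackward")]]
NumericVector inormBackward(NumericVector y, NumericVector sig,
                            NumericVector dy) {
  IntegerVector d = y.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int groups = d[2] * d[3];
  NumericVector dx(y.size());
  dx.attr("dim") = y.attr("dim");
  for (int g = 0; g < groups; ++g) {
    const double *ys = y.begin() + hw * g;
    const double *ds = dy.begin() + hw * g;
    double m1 = 0, m2 = 0;
    for (size_t i = 0; i < hw; ++i) { m1 += ds[i]; m2 += ds[i] * ys[i]; }
    m1 /= hw;
    m2 /= hw;
    double s = sig[g];
    double *o = dx.begin() + hw * g;
    for (size_t i = 0; i < hw; ++i) o[i] = (ds[i] - m1 - ys[i] * m2) / s;
  }
  return dx;
}

// For each point in A (rows, physical mm coordinates), the distance to the
// nearest point in B.  Brute force; surfaces at phantom scale are small.
// [[Rcpp::export(name = ".nnDistances")]]
NumericVector nnDistances(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double a1 = A(i, 0), a2 = A(i, 1), a3 = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double d1 = a1 - B(j, 0), d2 = a2 - B(j, 1), d3 = a3 - B(j, 2);
      double d = d1 * d1 + d2 * d2 + d3 * d3;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
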