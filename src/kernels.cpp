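// Low-level CPU kernels for the segmentation networks and the level-set
// preprocessing. Tensor layout is column-major (H, W, C, N), matching R
// arrays; convolution weights are (k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat weight_matrix(const NumericVector &w,
                                      int k, int cin, int cout) {
  // (Cout x k*k*Cin), patch flattening (di, dj, ci) with di fastest
  arma::mat W(cout, k * k * cin);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          W(co, di + k * (dj + k * ci)) =
            w[di + k * (dj + k * (ci + cin * co))];
  return W;
}

static inline void im2col(const double *x, int H, int Wd, int C,
                          int k, int stride, int pad,
                          int Ho, int Wo, arma::mat &col) {
  // col: (k*k*C) x (Ho*Wo)
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int cidx = ho + Ho * wo;
      const int i0 = ho * stride - pad;
      const int j0 = wo * stride - pad;
      for (int ci = 0; ci < C; ++ci) {
        for (int dj = 0; dj < k; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= Wd) continue;
          for (int di = 0; di < k; ++di) {
            const int i = i0 + di;
            if (i < 0 || i >= H) continue;
            col(di + k * (dj + k * ci), cidx) = x[i + H * (j + Wd * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dFwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], cin = wd[2], cout = wd[3];
  if (cin != C) stop("conv2d: channel mismatch");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  arma::mat Wm = weight_matrix(w, k, cin, cout);
  arma::mat col(k * k * C, Ho * Wo);
  NumericVector y(Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const int planeX = H * Wd * C, planeY = Ho * Wo * cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * planeX, H, Wd, C, k, stride, pad, Ho, Wo, col);
    arma::mat res = Wm * col;  // (Cout x Ho*Wo)
    double *yp = y.begin() + (R_xlen_t)n * planeY;
    for (int co = 0; co < cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        yp[p + Ho * Wo * co] = res(co, p) + b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], cin = wd[2], cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  arma::mat Wm = weight_matrix(w, k, cin, cout);
  arma::mat col(k * k * C, Ho * Wo);
  arma::mat dW(cout, k * k * cin, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)H * Wd * C * N);
    dx.attr("dim") = IntegerVector::create(H, Wd, C, N);
  }
  const int planeX = H * Wd * C, planeY = Ho * Wo * cout;
  arma::mat dyn(cout, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double *dyp = dy.begin() + (R_xlen_t)n * planeY;
    for (int co = 0; co < cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        dyn(co, p) = dyp[p + Ho * Wo * co];
    im2col(x.begin() + (R_xlen_t)n * planeX, H, Wd, C, k, stride, pad, Ho, Wo, col);
    dW += dyn * col.t();
    db += arma::sum(dyn, 1);
    if (need_dx) {
      arma::mat dcol = Wm.t() * dyn;  // (k*k*C) x (Ho*Wo)
      double *dxp = dx.begin() + (R_xlen_t)n * planeX;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int cidx = ho + Ho * wo;
          const int i0 = ho * stride - pad;
          const int j0 = wo * stride - pad;
          for (int ci = 0; ci < C; ++ci)
            for (int dj = 0; dj < k; ++dj) {
              const int j = j0 + dj;
              if (j < 0 || j >= Wd) continue;
              for (int di = 0; di < k; ++di) {
                const int i = i0 + di;
                if (i < 0 || i >= H) continue;
                dxp[i + H * (j + Wd * ci)] += dcol(di + k * (dj + k * ci), cidx);
              }
            }
        }
      }
    }
  }
  NumericVector dwR((R_xlen_t)k * k * cin * cout);
  dwR.attr("dim") = IntegerVector::create(k, k, cin, cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          dwR[di + k * (dj + k * (ci + cin * co))] =
            dW(co, di + k * (dj + k * ci));
  NumericVector dbR(cout);
  for (int co = 0; co < cout; ++co) dbR[co] = db(co);
  if (need_dx) return List::create(_["dw"] = dwR, _["db"] = dbR, _["dx"] = dx);
  return List::create(_["dw"] = dwR, _["db"] = dbR);
}

// [[Rcpp::export(name = ".maxpool2Fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = Wd / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);  // 0-based index in (H,W) plane
  y.attr("dim") = idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (R_xlen_t)(c + C * n) * H * Wd;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY; int barg = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int p = (2 * ho + di) + H * (2 * wo + dj);
              if (xp[p] > best) { best = xp[p]; barg = p; }
            }
          // column-major within the (Ho,Wo,C,N) block: position computed below
          y[(R_xlen_t)(ho + Ho * (wo + Wo * (c + C * n)))] = best;
          idx[(R_xlen_t)(ho + Ho * (wo + Wo * (c + C * n)))] = barg;
          (void)q;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2Bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int Wd) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((R_xlen_t)H * Wd * C * N);
  dx.attr("dim") = IntegerVector::create(H, Wd, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dxp = dx.begin() + (R_xlen_t)(c + C * n) * H * Wd;
      const R_xlen_t off = (R_xlen_t)(c + C * n) * Ho * Wo;
      for (R_xlen_t p = 0; p < (R_xlen_t)Ho * Wo; ++p)
        dxp[idx[off + p]] += dy[off + p];
    }
  return dx;
}

// [[Rcpp::export(name = ".upsample2Fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * Wd;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (R_xlen_t)(c + C * n) * H * Wd;
      double *yp = y.begin() + (R_xlen_t)(c + C * n) * Ho * Wo;
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = xp[i + H * j];
          yp[2 * i     + Ho * (2 * j)]     = v;
          yp[2 * i + 1 + Ho * (2 * j)]     = v;
          yp[2 * i     + Ho * (2 * j + 1)] = v;
          yp[2 * i + 1 + Ho * (2 * j + 1)] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2Bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, Wd = Wo / 2;
  NumericVector dx((R_xlen_t)H * Wd * C * N);
  dx.attr("dim") = IntegerVector::create(H, Wd, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dyp = dy.begin() + (R_xlen_t)(c + C * n) * Ho * Wo;
      double *dxp = dx.begin() + (R_xlen_t)(c + C * n) * H * Wd;
      for (int j = 0; j < Wd; ++j)
        for (int i = 0; i < H; ++i)
          dxp[i + H * j] = dyp[2 * i + Ho * (2 * j)] +
                           dyp[2 * i + 1 + Ho * (2 * j)] +
                           dyp[2 * i + Ho * (2 * j + 1)] +
                           dyp[2 * i + 1 + Ho * (2 * j + 1)];
    }
  return dx;
}

// Zero-padded separable 2-D convolution of a single-plane image; kernels are
// odd-length vectors applied along rows (dim 1) then columns (dim 2).
// [[Rcpp::export(name = ".sepConv2")]]
NumericMatrix sepconv2(NumericMatrix img, NumericVector krow, NumericVector kcol) {
  const int H = img.nrow(), W = img.ncol();
  const int rr = (krow.size() - 1) / 2, rc = (kcol.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -rr; d <= rr; ++d) {
        const int ii = i + d;
        if (ii < 0 || ii >= H) continue;
        s += krow[d + rr] * img(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -rc; d <= rc; ++d) {
        const int jj = j + d;
        if (jj < 0 || jj >= W) continue;
        s += kcol[d + rc] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// Full 2-D convolution (correlation with a symmetric kernel); boundary is
// either zero padding or edge replication.
// [[Rcpp::export(name = ".conv2Full")]]
NumericMatrix conv2_full(NumericMatrix img, NumericMatrix ker, bool replicate) {
  const int H = img.nrow(), W = img.ncol();
  const int rr = (ker.nrow() - 1) / 2, rc = (ker.ncol() - 1) / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int dj = -rc; dj <= rc; ++dj) {
        int jj = j + dj;
        if (replicate) jj = jj < 0 ? 0 : (jj >= W ? W - 1 : jj);
        else if (jj < 0 || jj >= W) continue;
        for (int di = -rr; di <= rr; ++di) {
          int ii = i + di;
          if (replicate) ii = ii < 0 ? 0 : (ii >= H ? H - 1 : ii);
          else if (ii < 0 || ii >= H) continue;
          s += ker(di + rr, dj + rc) * img(ii, jj);
        }
      }
      out(i, j) = s;
    }
  return out;
}
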