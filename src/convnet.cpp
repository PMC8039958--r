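// Numerical kernels for the patch CNN and polygon rasterization.
// Tensor layout everywhere: column-major R arrays dim (H, W, C, N).
// Conv weights: matrix (ks*ks*Cin) x Cout with row index k = kh + ks*kw + ks*ks*c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transposed im2col: colT is P x K with P = Ho*Wo*N (p = ho + Ho*wo +
// Ho*Wo*n) and K = ks*ks*C (k = kh + ks*kw + ks*ks*c). Writing down column
// k while scanning p keeps writes contiguous.
static void im2colT(const double* xp, int H, int W, int C, int N,
                    int ks, int stride, int pad, arma::mat& colT,
                    int Ho, int Wo) {
  const long HW = (long)H * W;
  const long HoWo = (long)Ho * Wo;
  for (int c = 0; c < C; c++) {
    for (int kw = 0; kw < ks; kw++) {
      for (int kh = 0; kh < ks; kh++) {
        double* dst = colT.colptr(kh + ks * kw + (long)ks * ks * c);
        for (int n = 0; n < N; n++) {
          const double* xc = xp + HW * c + HW * C * n;
          for (int wo = 0; wo < Wo; wo++) {
            int wc = wo * stride - pad + kw;
            long pbase = (long)Ho * wo + HoWo * n;
            if (wc < 0 || wc >= W) {
              for (int ho = 0; ho < Ho; ho++) dst[pbase + ho] = 0.0;
              continue;
            }
            const double* xcol = xc + (long)H * wc;
            for (int ho = 0; ho < Ho; ho++) {
              int hc = ho * stride - pad + kh;
              dst[pbase + ho] = (hc < 0 || hc >= H) ? 0.0 : xcol[hc];
            }
          }
        }
      }
    }
  }
}

// Forward convolution. Returns the output and (when keep_col) the im2col
// matrix for reuse in the backward pass.
// [[Rcpp::export]]
List conv2d_fwd_full(NumericVector x, NumericMatrix w,
                     int ks, int stride, int pad, bool keep_col) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = ks * ks * C, Cout = w.ncol();
  if (w.nrow() != K) stop("weight/input channel mismatch");
  int Ho = (H + 2 * pad - ks) / stride + 1;
  int Wo = (W + 2 * pad - ks) / stride + 1;
  long P = (long)Ho * Wo * N;
  NumericMatrix colR(P, K);
  arma::mat colT(colR.begin(), P, K, false);
  im2colT(x.begin(), H, W, C, N, ks, stride, pad, colT, Ho, Wo);
  arma::mat wm(w.begin(), K, Cout, false);
  arma::mat ym = colT * wm;  // P x Cout
  NumericVector y((long)Ho * Wo * Cout * N);
  double* yp = y.begin();
  const long HoWo = (long)Ho * Wo;
  for (int co = 0; co < Cout; co++) {
    const double* src = ym.colptr(co);
    for (int n = 0; n < N; n++) {
      double* ydst = yp + HoWo * co + HoWo * Cout * n;
      const double* ysrc = src + HoWo * n;
      std::copy(ysrc, ysrc + HoWo, ydst);
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  if (!keep_col) return List::create(_["y"] = y);
  return List::create(_["y"] = y, _["col"] = colR);
}

// compatibility wrapper returning just the output array
// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w,
                         int ks, int stride, int pad) {
  List r = conv2d_fwd_full(x, w, ks, stride, pad, false);
  return r["y"];
}

// Backward convolution. `colT` is the cached P x K im2col matrix from the
// forward pass (recomputed from x when an empty matrix is passed).
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int ks, int stride, int pad,
                Rcpp::Nullable<NumericMatrix> colT_ = R_NilValue) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  int K = ks * ks * C;
  long P = (long)Ho * Wo * N;
  const long HoWo = (long)Ho * Wo;
  // gather dy into P x Cout
  arma::mat dym(P, Cout);
  const double* dyp = dy.begin();
  for (int co = 0; co < Cout; co++) {
    double* dst = dym.colptr(co);
    for (int n = 0; n < N; n++) {
      const double* src = dyp + HoWo * co + HoWo * Cout * n;
      std::copy(src, src + HoWo, dst + HoWo * n);
    }
  }
  arma::mat wm(w.begin(), K, Cout, false);
  arma::mat dw;
  if (colT_.isNotNull()) {
    NumericMatrix colR(colT_);
    arma::mat colT(colR.begin(), P, K, false);
    dw = colT.t() * dym;                  // K x Cout
  } else {
    arma::mat colT(P, K);
    im2colT(x.begin(), H, W, C, N, ks, stride, pad, colT, Ho, Wo);
    dw = colT.t() * dym;
  }
  arma::mat dcolT = dym * wm.t();         // P x K
  // col2im scatter-add, mirroring im2colT's traversal
  NumericVector dx((long)H * W * C * N);
  double* dxp = dx.begin();
  const long HW = (long)H * W;
  for (int c = 0; c < C; c++) {
    for (int kw = 0; kw < ks; kw++) {
      for (int kh = 0; kh < ks; kh++) {
        const double* src = dcolT.colptr(kh + ks * kw + (long)ks * ks * c);
        for (int n = 0; n < N; n++) {
          double* xc = dxp + HW * c + HW * C * n;
          for (int wo = 0; wo < Wo; wo++) {
            int wc = wo * stride - pad + kw;
            if (wc < 0 || wc >= W) continue;
            double* xcol = xc + (long)H * wc;
            long pbase = (long)Ho * wo + HoWo * n;
            for (int ho = 0; ho < Ho; ho++) {
              int hc = ho * stride - pad + kh;
              if (hc >= 0 && hc < H) xcol[hc] += src[pbase + ho];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  NumericMatrix dwR(K, Cout);
  std::copy(dw.memptr(), dw.memptr() + dw.n_elem, dwR.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwR);
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector rmean, NumericVector rvar,
            double eps, double momentum, bool training) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const long HW = (long)H * W;
  const long M = HW * N;
  NumericVector y(x.size());
  NumericVector mean(C), var(C), invstd(C);
  const double* xp = x.begin();
  if (training) {
    for (int c = 0; c < C; c++) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; n++) {
        const double* xc = xp + HW * c + HW * C * n;
        for (long q = 0; q < HW; q++) { s += xc[q]; s2 += xc[q] * xc[q]; }
      }
      double m = s / M;
      double v = s2 / M - m * m;
      if (v < 0) v = 0;
      mean[c] = m; var[c] = v;
      invstd[c] = 1.0 / std::sqrt(v + eps);
    }
  } else {
    for (int c = 0; c < C; c++) {
      mean[c] = rmean[c]; var[c] = rvar[c];
      invstd[c] = 1.0 / std::sqrt(rvar[c] + eps);
    }
  }
  NumericVector xhat(training ? x.size() : 0);
  double* yp = y.begin();
  double* xhp = training ? xhat.begin() : nullptr;
  for (int c = 0; c < C; c++) {
    const double m = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; n++) {
      const long off = HW * c + HW * C * n;
      const double* xc = xp + off;
      double* yc = yp + off;
      if (training) {
        double* hc = xhp + off;
        for (long q = 0; q < HW; q++) {
          double h = (xc[q] - m) * is;
          hc[q] = h;
          yc[q] = g * h + b;
        }
      } else {
        for (long q = 0; q < HW; q++)
          yc[q] = g * (xc[q] - m) * is + b;
      }
    }
  }
  y.attr("dim") = xd;
  NumericVector nrm(C), nrv(C);
  if (training) {
    xhat.attr("dim") = xd;
    for (int c = 0; c < C; c++) {
      nrm[c] = (1 - momentum) * rmean[c] + momentum * mean[c];
      // unbiased variance for running estimate
      double vu = (M > 1) ? var[c] * (double)M / (M - 1) : var[c];
      nrv[c] = (1 - momentum) * rvar[c] + momentum * vu;
    }
  } else {
    nrm = rmean; nrv = rvar;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
            NumericVector gamma) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const long HW = (long)H * W;
  const long M = HW * N;
  NumericVector dgamma(C), dbeta(C);
  const double* dyp = dy.begin();
  const double* hp = xhat.begin();
  for (int c = 0; c < C; c++) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; n++) {
      const long off = HW * c + HW * C * n;
      const double* dc = dyp + off;
      const double* hc = hp + off;
      for (long q = 0; q < HW; q++) { sg += dc[q] * hc[q]; sb += dc[q]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
  }
  NumericVector dx(dy.size());
  double* dxp = dx.begin();
  for (int c = 0; c < C; c++) {
    const double k = gamma[c] * invstd[c];
    const double mb = dbeta[c] / M, mg = dgamma[c] / M;
    for (int n = 0; n < N; n++) {
      const long off = HW * c + HW * C * n;
      const double* dc = dyp + off;
      const double* hc = hp + off;
      double* xc = dxp + off;
      for (long q = 0; q < HW; q++)
        xc[q] = k * (dc[q] - mb - hc[q] * mg);
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Extract ws x ws patches (reflection padding with edge duplication) from a
// (H, W, C) channel stack at 1-based centers (rows, cols).
// [[Rcpp::export]]
NumericVector gather_patches(NumericVector img, IntegerVector rows,
                             IntegerVector cols, int ws) {
  IntegerVector xd = img.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int Np = rows.size();
  int half = ws / 2;
  NumericVector out((long)ws * ws * C * Np);
  const double* ip = img.begin();
  double* op = out.begin();
  for (int n = 0; n < Np; n++) {
    int r0 = rows[n] - 1, c0 = cols[n] - 1;
    for (int c = 0; c < C; c++) {
      for (int dw = -half; dw <= half; dw++) {
        int wc = c0 + dw;
        if (wc < 0) wc = -wc - 1;
        if (wc >= W) wc = 2 * W - wc - 1;
        for (int dh = -half; dh <= half; dh++) {
          int hc = r0 + dh;
          if (hc < 0) hc = -hc - 1;
          if (hc >= H) hc = 2 * H - hc - 1;
          op[(dh + half) + (long)ws * (dw + half) + (long)ws * ws * c +
             (long)ws * ws * C * n] = ip[hc + (long)H * wc + (long)H * W * c];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ws, ws, C, Np);
  return out;
}

static void bres_line(int r0, int c0, int r1, int c1,
                      std::vector<int>& rr, std::vector<int>& cc) {
  int dr = std::abs(r1 - r0), dc = std::abs(c1 - c0);
  int sr = (r0 < r1) ? 1 : -1, sc = (c0 < c1) ? 1 : -1;
  int err = (dc > dr ? dc : -dr) / 2;
  int r = r0, c = c0;
  while (true) {
    rr.push_back(r); cc.push_back(c);
    if (r == r1 && c == c1) break;
    int e2 = err;
    if (e2 > -dc) { err -= dr; c += sc; }
    if (e2 < dr)  { err += dc; r += sr; }
  }
}

// [[Rcpp::export]]
IntegerMatrix bresenham_cpp(int r0, int c0, int r1, int c1) {
  std::vector<int> rr, cc;
  bres_line(r0, c0, r1, c1, rr, cc);
  IntegerMatrix out(rr.size(), 2);
  for (size_t i = 0; i < rr.size(); i++) { out(i, 0) = rr[i]; out(i, 1) = cc[i]; }
  return out;
}

// Fill one polygon: Bresenham boundary (rounded vertices) OR'd with the
// even-odd scanline interior at integer pixel centers (0-based coords).
// Pixels outside the canvas are silently dropped (caller warns on clipping).
// [[Rcpp::export]]
LogicalMatrix fill_polygon_cpp(NumericMatrix verts, int nrow, int ncol) {
  LogicalMatrix out(nrow, ncol);
  int V = verts.nrow();
  if (V < 3) return out;
  // boundary
  std::vector<int> rr, cc;
  for (int i = 0; i < V; i++) {
    int j = (i + 1) % V;
    bres_line((int)std::lround(verts(i, 0)), (int)std::lround(verts(i, 1)),
              (int)std::lround(verts(j, 0)), (int)std::lround(verts(j, 1)),
              rr, cc);
  }
  for (size_t i = 0; i < rr.size(); i++)
    if (rr[i] >= 0 && rr[i] < nrow && cc[i] >= 0 && cc[i] < ncol)
      out(rr[i], cc[i]) = true;
  // interior: even-odd per row; a pixel (y, x) is interior when the number
  // of edge crossings with x-intercept strictly greater than x is odd
  for (int y = 0; y < nrow; y++) {
    std::vector<double> xs;
    for (int i = 0; i < V; i++) {
      int j = (i + 1) % V;
      double r1 = verts(i, 0), c1 = verts(i, 1);
      double r2 = verts(j, 0), c2 = verts(j, 1);
      if ((r1 <= y && r2 > y) || (r2 <= y && r1 > y)) {
        double xi = c1 + (y - r1) * (c2 - c1) / (r2 - r1);
        xs.push_back(xi);
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    // crossings > x odd  <=>  x in [xs[2k], xs[2k+1])
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int x0 = (int)std::ceil(xs[k]);
      for (int x = std::max(x0, 0); x < xs[k + 1] && x < ncol; x++)
        out(y, x) = true;
    }
  }
  return out;
}
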