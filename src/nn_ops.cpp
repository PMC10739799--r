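// Low-level numerical kernels for the CPU training engine and morphometry.
// Feature maps are R arrays of dim (H, W, C, N), column-major; convolution
// weights are arrays of dim (kh, kw, Cin, Cout) whose memory layout matches
// the im2col row ordering, so the convolution reduces to one GEMM per sample.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Extract padded patches of x[, , , n] into a (kh*kw*Cin) x (H*W) matrix.
// Same-size output: pad_top = (kh-1)/2, pad_left = (kw-1)/2 (floor), which
// also handles even kernels with asymmetric padding.
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, arma::mat &cols) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        double *out = cols.memptr() + row; // stride kh*kw*C between columns
        const int rs = (int)cols.n_rows;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pl;
          const bool wok = (sw >= 0 && sw < W);
          const double *src = x + c * HW + sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - pt;
            double v = 0.0;
            if (wok && sh >= 0 && sh < H) v = src[sh];
            out[(size_t)(h + H * w) * rs] = v;
          }
        }
      }
    }
  }
}

// Scatter-add the column matrix back into a (H, W, C) image (adjoint of im2col).
static void col2im(const arma::mat &cols, int H, int W, int C,
                   int kh, int kw, double *x) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  const int HW = H * W;
  const int rs = (int)cols.n_rows;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        const double *in = cols.memptr() + row;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pl;
          if (sw < 0 || sw >= W) continue;
          double *dst = x + c * HW + sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + ki - pt;
            if (sh < 0 || sh >= H) continue;
            dst[sh] += in[(size_t)(h + H * w) * rs];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must have dim (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input channels do not match weight Cin");
  if ((int)b.size() != Cout) stop("bias length must equal Cout");

  NumericVector y = make4(H, W, Cout, N);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat cols((size_t)kh * kw * Cin, (size_t)H * W);
  const size_t in_stride = (size_t)H * W * C, out_stride = (size_t)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * in_stride, H, W, C, kh, kw, cols);
    arma::mat Ym(y.begin() + n * out_stride, (size_t)H * W, Cout, false, true);
    Ym = cols.t() * Wm;
    for (int co = 0; co < Cout; ++co) Ym.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input channels do not match weight Cin");

  NumericVector dx = make4(H, W, C, N);
  NumericVector dw = make4(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat cols((size_t)kh * kw * Cin, (size_t)H * W);
  const size_t in_stride = (size_t)H * W * C, out_stride = (size_t)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * in_stride, H, W, C, kh, kw, cols);
    arma::mat dYm(dy.begin() + n * out_stride, (size_t)H * W, Cout, false, true);
    dWm += cols * dYm;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dYm.col(co));
    arma::mat dcols = Wm * dYm.t();
    col2im(dcols, H, W, C, kh, kw, dx.begin() + n * in_stride);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max-pooling with stride 2; records the winning flat index for backprop.
// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double *px = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t best = i00; double bv = px[i00];
          const size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
          y[o] = bv; idx[o] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  NumericVector dx = make4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

static inline void lin_w(int d, int S, int &i0, int &i1, double &w1) {
  // source coordinate for 2x upsampling, align_corners = FALSE convention
  double s = (d + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > S - 1) s = S - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, S - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4(Ho, Wo, C, N);
  const double *px = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        int j0, j1; double wj;
        lin_w(w, W, j0, j1, wj);
        for (int h = 0; h < Ho; ++h, ++o) {
          int i0, i1; double wi;
          lin_w(h, H, i0, i1, wi);
          y[o] = (1 - wi) * (1 - wj) * px[base + (size_t)j0 * H + i0] +
                 wi * (1 - wj) * px[base + (size_t)j0 * H + i1] +
                 (1 - wi) * wj * px[base + (size_t)j1 * H + i0] +
                 wi * wj * px[base + (size_t)j1 * H + i1];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bwd(NumericVector dy) {
  int Ho, Wo, C, N; get_dims4(dy, Ho, Wo, C, N);
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx = make4(H, W, C, N);
  double *pdx = dx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        int j0, j1; double wj;
        lin_w(w, W, j0, j1, wj);
        for (int h = 0; h < Ho; ++h, ++o) {
          int i0, i1; double wi;
          lin_w(h, H, i0, i1, wi);
          const double g = dy[o];
          pdx[base + (size_t)j0 * H + i0] += (1 - wi) * (1 - wj) * g;
          pdx[base + (size_t)j0 * H + i1] += wi * (1 - wj) * g;
          pdx[base + (size_t)j1 * H + i0] += (1 - wi) * wj * g;
          pdx[base + (size_t)j1 * H + i1] += wi * wj * g;
        }
      }
    }
  return dx;
}

// 8-connected component labelling of a binary matrix (BFS flood fill).
// Labels are assigned in raster (column-major) order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cc_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      lab(h, w) = ++next;
      q.push(std::make_pair(h, w));
      while (!q.empty()) {
        const int ch = q.front().first, cw = q.front().second;
        q.pop();
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            if (!dh && !dw) continue;
            const int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              q.push(std::make_pair(nh, nw));
            }
          }
      }
    }
  return lab;
}
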