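// Low-level numerical kernels: 2-D convolution (im2col + GEMM), bilinear
// resizing with its adjoint, mask-restricted sliding-window statistics,
// a bilateral filter, 4-connected component labelling, nearest-neighbour
// affine warping, and the convex-hull symmetric-difference objective used
// by the rigid registration. All arrays are (row, col[, channel]) and
// 0-based; callers convert from R's 1-based indexing.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col convolution, "same" output grid: Ho = ceil(H / stride)
// Column layout matches R's column-major flattening of a (kh, kw, Cin, Cout)
// weight array: kernel-row fastest, then kernel-col, then input channel.
// ---------------------------------------------------------------------------

static void conv_geometry(int H, int W, int kh, int kw, int stride, int dil,
                          int& Ho, int& Wo, int& pt, int& pl) {
  Ho = (H + stride - 1) / stride;
  Wo = (W + stride - 1) / stride;
  int eff_kh = (kh - 1) * dil + 1;
  int eff_kw = (kw - 1) * dil + 1;
  int pad_h = std::max(0, (Ho - 1) * stride + eff_kh - H);
  int pad_w = std::max(0, (Wo - 1) * stride + eff_kw - W);
  pt = pad_h / 2;
  pl = pad_w / 2;
}

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho, Wo, pt, pl;
  conv_geometry(H, W, kh, kw, stride, dil, Ho, Wo, pt, pl);
  arma::mat col(kh * kw * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = c * kh * kw + kj * kh + ki;
        for (int j = 0; j < Wo; ++j) {
          const int sc = j * stride - pl + kj * dil;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int sr = i * stride - pt + ki * dil;
            if (sr < 0 || sr >= H) continue;
            col(r, (size_t)j * Ho + i) = xc(sr, sc);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
List cpp_conv2d_fw(const arma::cube& x, const arma::mat& K, const arma::vec& b,
                   int kh, int kw, int stride, int dil,
                   bool return_col = false) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if ((int)K.n_rows != kh * kw * C)
    stop("weight/input channel mismatch: K has %d rows, expected %d",
         (int)K.n_rows, kh * kw * C);
  int Ho, Wo, pt, pl;
  conv_geometry(H, W, kh, kw, stride, dil, Ho, Wo, pt, pl);
  arma::mat col = im2col(x, kh, kw, stride, dil);
  arma::mat y = K.t() * col;           // Cout x (Ho*Wo)
  y.each_col() += b;
  const int Cout = K.n_cols;
  arma::cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.row(c), Ho, Wo);
  if (return_col)
    return List::create(_["y"] = out, _["col"] = col);
  return List::create(_["y"] = out);
}

// Backward pass. `col` may be the cached im2col matrix from the forward
// pass (pass a 0x0 matrix to rebuild from x); `want_dx = false` skips the
// input-gradient col2im for first layers.
// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::mat& K, const arma::cube& dy,
                   int kh, int kw, int stride, int dil,
                   bool want_dx = true,
                   Rcpp::Nullable<Rcpp::NumericMatrix> col_cache = R_NilValue) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  int Ho2, Wo2, pt, pl;
  conv_geometry(H, W, kh, kw, stride, dil, Ho2, Wo2, pt, pl);
  if (Ho != Ho2 || Wo != Wo2) stop("gradient shape mismatch");
  arma::mat col;
  if (col_cache.isNotNull()) {
    Rcpp::NumericMatrix cc(col_cache);
    col = arma::mat(cc.begin(), cc.nrow(), cc.ncol(), false);
  } else {
    col = im2col(x, kh, kw, stride, dil);
  }
  arma::mat dym(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dym.row(c) = arma::vectorise(dy.slice(c)).t();
  arma::mat dW = col * dym.t();                 // (kh*kw*C) x Cout
  arma::vec db = arma::sum(dym, 1);
  if (!want_dx)
    return List::create(_["dW"] = dW, _["db"] = db);
  arma::mat dcol = K * dym;                     // (kh*kw*C) x (Ho*Wo)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& dxc = dx.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = c * kh * kw + kj * kh + ki;
        for (int j = 0; j < Wo; ++j) {
          const int sc = j * stride - pl + kj * dil;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int sr = i * stride - pt + ki * dil;
            if (sr < 0 || sr >= H) continue;
            dxc(sr, sc) += dcol(r, (size_t)j * Ho + i);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Bilinear resize (align-corners) and its adjoint.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const double sr = (Ho > 1) ? (double)(H - 1) / (Ho - 1) : 0.0;
  const double sc = (Wo > 1) ? (double)(W - 1) / (Wo - 1) : 0.0;
  arma::cube out(Ho, Wo, C);
  for (int j = 0; j < Wo; ++j) {
    const double yc = j * sc;
    const int c0 = std::min((int)std::floor(yc), W - 1);
    const int c1 = std::min(c0 + 1, W - 1);
    const double wc = yc - c0;
    for (int i = 0; i < Ho; ++i) {
      const double yr = i * sr;
      const int r0 = std::min((int)std::floor(yr), H - 1);
      const int r1 = std::min(r0 + 1, H - 1);
      const double wr = yr - r0;
      for (int ch = 0; ch < C; ++ch) {
        const arma::mat& xc = x.slice(ch);
        out(i, j, ch) =
          (1 - wr) * (1 - wc) * xc(r0, c0) + (1 - wr) * wc * xc(r0, c1) +
          wr * (1 - wc) * xc(r1, c0) + wr * wc * xc(r1, c1);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_adj(const arma::cube& dy, int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  const double sr = (Ho > 1) ? (double)(H - 1) / (Ho - 1) : 0.0;
  const double sc = (Wo > 1) ? (double)(W - 1) / (Wo - 1) : 0.0;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    const double yc = j * sc;
    const int c0 = std::min((int)std::floor(yc), W - 1);
    const int c1 = std::min(c0 + 1, W - 1);
    const double wc = yc - c0;
    for (int i = 0; i < Ho; ++i) {
      const double yr = i * sr;
      const int r0 = std::min((int)std::floor(yr), H - 1);
      const int r1 = std::min(r0 + 1, H - 1);
      const double wr = yr - r0;
      for (int ch = 0; ch < C; ++ch) {
        const double g = dy(i, j, ch);
        dx(r0, c0, ch) += (1 - wr) * (1 - wc) * g;
        dx(r0, c1, ch) += (1 - wr) * wc * g;
        dx(r1, c0, ch) += wr * (1 - wc) * g;
        dx(r1, c1, ch) += wr * wc * g;
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Mask-restricted sliding-window statistics over a symmetric (2r+1)^2 window
// clipped at the image border (no padding: reflected or replicated borders
// would double-count pixels and break the window->global consistency).
// Pixels whose window contains no in-mask pixel get count 0 and NaN
// statistics (imputed by the caller).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_window_stats(const arma::mat& slice, const arma::imat& mask, int radius) {
  const int H = slice.n_rows, W = slice.n_cols;
  arma::mat mx(H, W), mn(H, W), md(H, W);
  arma::imat cnt(H, W);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      buf.clear();
      double s = 0.0, vmax = -INFINITY;
      const int j0 = std::max(0, j - radius), j1 = std::min(W - 1, j + radius);
      const int i0 = std::max(0, i - radius), i1 = std::min(H - 1, i + radius);
      for (int cj = j0; cj <= j1; ++cj) {
        for (int ci = i0; ci <= i1; ++ci) {
          if (mask(ci, cj)) {
            const double v = slice(ci, cj);
            buf.push_back(v);
            s += v;
            if (v > vmax) vmax = v;
          }
        }
      }
      const int n = buf.size();
      cnt(i, j) = n;
      if (n == 0) {
        mx(i, j) = mn(i, j) = md(i, j) = NA_REAL;
      } else {
        mx(i, j) = vmax;
        mn(i, j) = s / n;
        const int h = n / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.end());
        double m = buf[h];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + h);
          m = 0.5 * (m + lo);
        }
        md(i, j) = m;
      }
    }
  }
  return List::create(_["max"] = mx, _["mean"] = mn, _["median"] = md,
                      _["count"] = cnt);
}

// [[Rcpp::export]]
arma::mat cpp_bilateral(const arma::mat& slice, const arma::imat& mask,
                        double sigma_s, double sigma_r) {
  const int H = slice.n_rows, W = slice.n_cols;
  const int radius = (int)std::ceil(2.0 * sigma_s);
  arma::mat out(H, W, arma::fill::zeros);
  const double is2 = 1.0 / (2.0 * sigma_s * sigma_s);
  const double ir2 = 1.0 / (2.0 * sigma_r * sigma_r);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      const double v0 = slice(i, j);
      double num = 0.0, den = 0.0;
      const int i0 = std::max(0, i - radius), i1 = std::min(H - 1, i + radius);
      const int j0 = std::max(0, j - radius), j1 = std::min(W - 1, j + radius);
      for (int jj = j0; jj <= j1; ++jj) {
        for (int ii = i0; ii <= i1; ++ii) {
          if (!mask(ii, jj)) continue;
          const double v = slice(ii, jj);
          const double d2 = (double)(ii - i) * (ii - i) + (double)(jj - j) * (jj - j);
          const double w = std::exp(-d2 * is2 - (v - v0) * (v - v0) * ir2);
          num += w * v;
          den += w;
        }
      }
      out(i, j) = num / den;   // centre pixel always contributes: den > 0
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 4-connected component labelling and border-flood hole filling.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::imat cpp_label4(const arma::imat& mask) {
  const int H = mask.n_rows, W = mask.n_cols;
  arma::imat lab(H, W, arma::fill::zeros);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(j * H + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        const int ni[4] = {pi - 1, pi + 1, pi, pi};
        const int nj[4] = {pj, pj, pj - 1, pj + 1};
        for (int k = 0; k < 4; ++k) {
          if (ni[k] < 0 || ni[k] >= H || nj[k] < 0 || nj[k] >= W) continue;
          if (mask(ni[k], nj[k]) && !lab(ni[k], nj[k])) {
            lab(ni[k], nj[k]) = next;
            stack.push_back(nj[k] * H + ni[k]);
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
arma::imat cpp_fill_holes(const arma::imat& mask) {
  const int H = mask.n_rows, W = mask.n_cols;
  arma::imat outside(H, W, arma::fill::zeros);
  std::vector<int> stack;
  auto push = [&](int i, int j) {
    if (i >= 0 && i < H && j >= 0 && j < W && !mask(i, j) && !outside(i, j)) {
      outside(i, j) = 1;
      stack.push_back(j * H + i);
    }
  };
  for (int i = 0; i < H; ++i) { push(i, 0); push(i, W - 1); }
  for (int j = 0; j < W; ++j) { push(0, j); push(H - 1, j); }
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int pi = p % H, pj = p / H;
    push(pi - 1, pj); push(pi + 1, pj); push(pi, pj - 1); push(pi, pj + 1);
  }
  arma::imat filled(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      filled(i, j) = mask(i, j) || !outside(i, j);
  return filled;
}

// ---------------------------------------------------------------------------
// Nearest-neighbour affine warp for integer maps. A is a 2x3 matrix mapping a
// target pixel centre (r, c, 1) (0-based) to source (r, c) coordinates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::imat cpp_warp_nn(const arma::imat& src, const arma::mat& A,
                       int Ht, int Wt, int fill) {
  const int H = src.n_rows, W = src.n_cols;
  arma::imat out(Ht, Wt);
  for (int j = 0; j < Wt; ++j) {
    for (int i = 0; i < Ht; ++i) {
      const double sr = A(0, 0) * i + A(0, 1) * j + A(0, 2);
      const double sc = A(1, 0) * i + A(1, 1) * j + A(1, 2);
      const int ri = (int)std::lround(sr);
      const int ci = (int)std::lround(sc);
      out(i, j) = (ri >= 0 && ri < H && ci >= 0 && ci < W) ? src(ri, ci) : fill;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Convex-polygon row intervals and the symmetric-difference area objective.
// Vertices are (row, col) pairs; a convex polygon meets a horizontal line in
// at most one interval, so the symmetric-difference area is a 1-D integral
// of interval mismatches over rows.
// ---------------------------------------------------------------------------

static bool row_interval(const arma::mat& v, double y, double& x0, double& x1) {
  const int n = v.n_rows;
  bool any = false;
  x0 = INFINITY; x1 = -INFINITY;
  for (int k = 0; k < n; ++k) {
    const double y1 = v(k, 0), x1v = v(k, 1);
    const double y2 = v((k + 1) % n, 0), x2v = v((k + 1) % n, 1);
    if ((y1 <= y) == (y2 <= y)) continue;
    const double t = (y - y1) / (y2 - y1);
    const double x = x1v + t * (x2v - x1v);
    if (x < x0) x0 = x;
    if (x > x1) x1 = x;
    any = true;
  }
  return any;
}

static double symdiff_area(const arma::mat& vf, const arma::mat& vm, double step) {
  const double ylo = std::min(vf.col(0).min(), vm.col(0).min());
  const double yhi = std::max(vf.col(0).max(), vm.col(0).max());
  double acc = 0.0;
  for (double y = ylo + step / 2; y < yhi; y += step) {
    double a0, a1, b0, b1;
    const bool ina = row_interval(vf, y, a0, a1);
    const bool inb = row_interval(vm, y, b0, b1);
    if (!ina && !inb) continue;
    if (!ina) { acc += (b1 - b0); continue; }
    if (!inb) { acc += (a1 - a0); continue; }
    const double inter = std::max(0.0, std::min(a1, b1) - std::max(a0, b0));
    acc += (a1 - a0) + (b1 - b0) - 2.0 * inter;
  }
  return acc * step;
}

// [[Rcpp::export]]
double cpp_symdiff_obj(const arma::mat& verts_fixed, const arma::mat& verts_moving,
                       double row_step) {
  return symdiff_area(verts_fixed, verts_moving, row_step);
}

// Grid search: verts_m0 are moving-hull vertices already scaled and centred
// (S * (v - c_m)); candidates rotate by theta (degrees), then shift by
// c_f + (ty, tx). Returns the objective for every (theta, tx, ty) triple.
// [[Rcpp::export]]
arma::cube cpp_reg_grid(const arma::mat& verts_fixed, const arma::mat& verts_m0,
                        const arma::vec& thetas, const arma::vec& txs,
                        const arma::vec& tys, double cfr, double cfc,
                        double row_step) {
  arma::cube obj(thetas.n_elem, txs.n_elem, tys.n_elem);
  arma::mat vt(verts_m0.n_rows, 2);
  for (arma::uword a = 0; a < thetas.n_elem; ++a) {
    const double th = thetas(a) * M_PI / 180.0;
    const double co = std::cos(th), si = std::sin(th);
    for (arma::uword k = 0; k < verts_m0.n_rows; ++k) {
      vt(k, 0) = co * verts_m0(k, 0) - si * verts_m0(k, 1);
      vt(k, 1) = si * verts_m0(k, 0) + co * verts_m0(k, 1);
    }
    for (arma::uword b = 0; b < txs.n_elem; ++b) {
      for (arma::uword c = 0; c < tys.n_elem; ++c) {
        arma::mat vshift = vt;
        vshift.col(0) += cfr + tys(c);
        vshift.col(1) += cfc + txs(b);
        obj(a, b, c) = symdiff_area(verts_fixed, vshift, row_step);
      }
    }
  }
  return obj;
}
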