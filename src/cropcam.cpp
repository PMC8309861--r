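// Low-level numerical kernels: 3x3 same-padding convolution (im2col + GEMM),
// 2x2 max-pooling, largest all-ones rectangle, 8-connected component labeling.
// All deterministic, single-threaded.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding 1.
// x: H x W x C cube. Result: (H*W) x (C*9); row r = i + j*H (column-major
// pixel order); column c*9 + (dj+1)*3 + (di+1) holds x(i+di, j+dj, c).
static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, C * 9, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        double* o = out.colptr(col);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = s.colptr(j + dj) + (i0 + di);
          double* dst = o + (i0 + (size_t)j * H);
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col3. dcol: (H*W) x (C*9) -> H x W x C cube.
static arma::cube col2im3(const arma::mat& dcol, int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& s = dx.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* o = dcol.colptr(col);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* dst = s.colptr(j + dj) + (i0 + di);
          const double* src = o + (i0 + (size_t)j * H);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return dx;
}

// Forward 3x3 same convolution. w: (Cin*9) x Cout, b: Cout.
// Returns out (H x W x Cout) and, when keep_cache, the im2col matrix.
// [[Rcpp::export]]
List cc_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                   const arma::vec& b, bool keep_cache) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat xc = im2col3(x);
  arma::mat y = xc * w;
  y.each_row() += b.t();
  arma::cube out(y.memptr(), H, W, Cout);  // copies; slice c = column c
  if (keep_cache)
    return List::create(_["out"] = out, _["xcol"] = xc);
  return List::create(_["out"] = out);
}

// Backward of cc_conv2d_fwd. dy: H x W x Cout.
// [[Rcpp::export]]
List cc_conv2d_bwd(const arma::cube& dy, const arma::mat& xcol,
                   const arma::mat& w, int cin) {
  const int H = dy.n_rows, W = dy.n_cols, Cout = dy.n_slices;
  arma::mat dy_mat(const_cast<double*>(dy.memptr()), (size_t)H * W, Cout,
                   false, true);
  arma::mat dw = xcol.t() * dy_mat;
  arma::vec db = arma::sum(dy_mat, 0).t();
  arma::mat dcol = dy_mat * w.t();
  arma::cube dx = col2im3(dcol, H, W, cin);
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// 2x2 stride-2 max pooling; H, W must be even. idx stores, per output
// element and channel, the within-slice linear index of the argmax (first
// occurrence wins on ties -> deterministic).
// [[Rcpp::export]]
List cc_maxpool2_fwd(const arma::cube& x, bool keep_cache) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::umat idx((size_t)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    arma::mat& o = out.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int ii = 2 * i, jj = 2 * j;
        double best = s(ii, jj);
        arma::uword bidx = ii + (arma::uword)jj * H;
        const int di[3] = {1, 0, 1}, dj[3] = {0, 1, 1};
        for (int t = 0; t < 3; ++t) {
          const double v = s(ii + di[t], jj + dj[t]);
          if (v > best) {
            best = v;
            bidx = (ii + di[t]) + (arma::uword)(jj + dj[t]) * H;
          }
        }
        o(i, j) = best;
        idx(i + (size_t)j * Ho, c) = bidx;
      }
    }
  }
  if (keep_cache)
    return List::create(_["out"] = out, _["idx"] = idx);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
arma::cube cc_maxpool2_bwd(const arma::cube& dy, const arma::umat& idx,
                           int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const size_t n = dy.n_rows * dy.n_cols;
  for (int c = 0; c < C; ++c) {
    const double* d = dy.slice(c).memptr();
    double* o = dx.slice(c).memptr();
    for (size_t r = 0; r < n; ++r) o[idx(r, c)] += d[r];
  }
  return dx;
}

// Largest all-ones axis-aligned rectangle in a 0/1 matrix, by the
// histogram-of-heights stack algorithm, restricted to rectangles of at
// least min_h x min_w (every admissible rectangle is contained in a
// maximal one the algorithm enumerates, so the restriction is exact).
// Ties on area broken by smaller top row, then smaller left column.
// Returns c(y0, x0, h, w) 0-based, or all -1 when no rectangle qualifies.
// [[Rcpp::export]]
IntegerVector cc_largest_rect(const IntegerMatrix& b, int min_h = 0,
                              int min_w = 0) {
  const int H = b.nrow(), W = b.ncol();
  std::vector<int> hgt(W, 0);
  long best_area = 0;
  int by0 = -1, bx0 = -1, bh = -1, bw = -1;
  std::vector<int> stack_x, stack_h;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) hgt[c] = b(r, c) ? hgt[c] + 1 : 0;
    stack_x.clear(); stack_h.clear();
    for (int c = 0; c <= W; ++c) {
      const int h = (c < W) ? hgt[c] : 0;
      int x = c;
      while (!stack_h.empty() && stack_h.back() >= h) {
        const int ph = stack_h.back(), px = stack_x.back();
        stack_h.pop_back(); stack_x.pop_back();
        const long area = (long)ph * (c - px);
        const int y0 = r - ph + 1;
        if (ph < min_h || (c - px) < min_w) { x = px; continue; }
        if (area > best_area ||
            (area == best_area && area > 0 &&
             (y0 < by0 || (y0 == by0 && px < bx0)))) {
          best_area = area; by0 = y0; bx0 = px; bh = ph; bw = c - px;
        }
        x = px;
      }
      stack_x.push_back(x); stack_h.push_back(h);
    }
  }
  return IntegerVector::create(by0, bx0, bh, bw);
}

// 8-connected component labeling of a 0/1 matrix by BFS. Labels are
// assigned 1,2,... in column-major scan order of each component's first
// pixel (deterministic).
// [[Rcpp::export]]
IntegerMatrix cc_label8(const IntegerMatrix& b) {
  const int H = b.nrow(), W = b.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qi, qj;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (b(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      size_t head = 0;
      while (head < qi.size()) {
        const int ci = qi[head], cj = qj[head];
        ++head;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (b(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              qi.push_back(ni); qj.push_back(nj);
            }
          }
        }
      }
    }
  }
  return lab;
}
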