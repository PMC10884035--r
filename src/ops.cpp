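// Low-level numerical kernels: 2-D convolution via im2col + BLAS,
// L1-penalized dynamic-programming boundary extraction, and a
// wrap-aware flood fill for hole removal in polar masks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Patch extraction for zero-padded convolution. Column q of the result
// enumerates (ki, kj, c) in R array order so that an R weight array of
// dim (k, k, Cin, Cout) flattens to the matching (k*k*Cin, Cout) matrix.
static mat im2col(const cube &x, int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(static_cast<uword>(Ho) * Wo, static_cast<uword>(k) * k * C,
           fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * stride + kj - pad;
          if (jin < 0 || jin >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * stride + ki - pad;
            if (iin < 0 || iin >= H) continue;
            cols(io + static_cast<uword>(Ho) * jo, q) = x(iin, jin, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube &x, const arma::mat &w,
                          const arma::vec &b, int k, int stride, int pad) {
  const int Ho = (static_cast<int>(x.n_rows) + 2 * pad - k) / stride + 1;
  const int Wo = (static_cast<int>(x.n_cols) + 2 * pad - k) / stride + 1;
  const int Cout = w.n_cols;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat y = cols * w;
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.col(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube &x, const arma::mat &w,
                          const arma::cube &dy, int k, int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat dymat(static_cast<uword>(Ho) * Wo, Cout);
  for (int c = 0; c < Cout; ++c) dymat.col(c) = vectorise(dy.slice(c));
  mat dw = cols.t() * dymat;
  vec db = sum(dymat, 0).t();
  mat dcols = dymat * w.t();
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * stride + kj - pad;
          if (jin < 0 || jin >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * stride + ki - pad;
            if (iin < 0 || iin >= H) continue;
            dx(iin, jin, c) += dcols(io + static_cast<uword>(Ho) * jo, q);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Lower envelope of D under the L1 transition penalty lambda*|dr|,
// computed with the classic two-pass recurrence.
static void minconv_l1(vec &m, double lambda) {
  const int H = m.n_elem;
  for (int r = 1; r < H; ++r) m(r) = std::min(m(r), m(r - 1) + lambda);
  for (int r = H - 2; r >= 0; --r) m(r) = std::min(m(r), m(r + 1) + lambda);
}

// Per-column boundary minimizing sum of cost plus lambda*|r_t - r_{t+1}|.
// Forward/backward message passing; with wrap = true the chain is
// traversed twice so messages reach circular stationarity and the result
// is equivariant under rotations of the column order.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_dp_boundary(const arma::mat &cost, double lambda,
                                    bool wrap) {
  const int H = cost.n_rows, n = cost.n_cols;
  mat F(H, n), G(H, n);
  const int loops = wrap ? 2 : 1;
  vec prev(H, fill::zeros);
  for (int L = 0; L < loops; ++L) {
    for (int t = 0; t < n; ++t) {
      vec m = prev;
      minconv_l1(m, lambda);
      vec cur = cost.col(t) + m;
      if (L == loops - 1) F.col(t) = cur;
      prev = cur - cur.min();
    }
  }
  prev.zeros();
  for (int L = 0; L < loops; ++L) {
    for (int t = n - 1; t >= 0; --t) {
      vec m = prev;
      minconv_l1(m, lambda);
      vec cur = cost.col(t) + m;
      if (L == loops - 1) G.col(t) = cur;
      prev = cur - cur.min();
    }
  }
  Rcpp::IntegerVector out(n);
  for (int t = 0; t < n; ++t) {
    vec tot = F.col(t) + G.col(t) - cost.col(t);
    out[t] = static_cast<int>(tot.index_min());
  }
  return out;
}

// Fill background components not 4-connected to the radial borders
// (rows 0 and H-1). theta (columns) is treated circularly when
// wrap_theta; otherwise the first/last columns also count as border.
// [[Rcpp::export]]
Rcpp::LogicalMatrix cpp_fill_holes(const Rcpp::LogicalMatrix &mask,
                                   bool wrap_theta) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> vis(static_cast<size_t>(H) * W, 0);
  std::vector<int> stack;
  stack.reserve(static_cast<size_t>(H) * W / 4);
  auto push = [&](int i, int j) {
    const int p = i + H * j;
    if (!mask(i, j) && !vis[p]) {
      vis[p] = 1;
      stack.push_back(p);
    }
  };
  for (int j = 0; j < W; ++j) {
    push(0, j);
    push(H - 1, j);
  }
  if (!wrap_theta) {
    for (int i = 0; i < H; ++i) {
      push(i, 0);
      push(i, W - 1);
    }
  }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int i = p % H, j = p / H;
    for (int t = 0; t < 4; ++t) {
      const int ni = i + di[t];
      int nj = j + dj[t];
      if (ni < 0 || ni >= H) continue;
      if (nj < 0 || nj >= W) {
        if (!wrap_theta) continue;
        nj = (nj + W) % W;
      }
      push(ni, nj);
    }
  }
  Rcpp::LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = mask(i, j) || !vis[i + H * j];
  return out;
}
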