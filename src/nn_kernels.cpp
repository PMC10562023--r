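// CNN primitives for the multi-branch GPR network: 3x3 convolution
// (stride 1, pad 0 or 1) and 3x3/3 max pooling, plus fused per-branch
// forward (embedding only) and backward (gradients only) entry points so
// the big intermediate feature maps never cross the R boundary.
// Everything is single-threaded and deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int K = 3; // kernel size, fixed

// im2col for a 3x3/stride-1 convolution. Column q = i + Ho*j holds the
// receptive field of output pixel (i, j); row r = di + 3*dj + 9*c matches the
// column-major layout of an R array dim c(3, 3, Cin, Cout).
static arma::mat im2col3(const arma::cube& x, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  arma::mat out(9 * Cin, (size_t)Ho * Wo, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const size_t q = (size_t)j * Ho + i;
      double* col = out.colptr(q);
      for (int c = 0; c < Cin; ++c) {
        const arma::mat& xs = x.slice(c);
        for (int dj = 0; dj < K; ++dj) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int di = 0; di < K; ++di) {
            const int ii = i + di - pad;
            if (ii < 0 || ii >= H) continue;
            col[9 * c + 3 * dj + di] = xs(ii, jj);
          }
        }
      }
    }
  }
  return out;
}

// scatter col2im: accumulate receptive-field gradients back onto the input
static void col2im3(const arma::mat& cols, int pad, int Ho, int Wo,
                    arma::cube& dx) {
  const int H = dx.n_rows, W = dx.n_cols, Cin = dx.n_slices;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const size_t q = (size_t)j * Ho + i;
      const double* col = cols.colptr(q);
      for (int c = 0; c < Cin; ++c) {
        arma::mat& dxs = dx.slice(c);
        for (int dj = 0; dj < K; ++dj) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int di = 0; di < K; ++di) {
            const int ii = i + di - pad;
            if (ii < 0 || ii >= H) continue;
            dxs(ii, jj) += col[9 * c + 3 * dj + di];
          }
        }
      }
    }
  }
}

struct ConvCtx { arma::mat cols; int Ho, Wo; };

static arma::cube conv_fw(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, int pad, ConvCtx* ctx) {
  const int Cout = Wm.n_cols;
  const int Ho = (int)x.n_rows + 2 * pad - (K - 1);
  const int Wo = (int)x.n_cols + 2 * pad - (K - 1);
  if (Ho < 1 || Wo < 1) stop("input too small for 3x3 convolution");
  arma::mat C = im2col3(x, pad, Ho, Wo);
  arma::mat Y = Wm.t() * C;
  Y.each_col() += b;
  arma::cube out(Ho, Wo, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = arma::reshape(Y.row(o), Ho, Wo);
  if (ctx) { ctx->cols = std::move(C); ctx->Ho = Ho; ctx->Wo = Wo; }
  return out;
}

// backward through a conv given its im2col context; fills dW (9Cin x Cout),
// db, and (if dx != null) the input gradient
static void conv_bw(const ConvCtx& ctx, const arma::mat& Wm,
                    const arma::cube& dy, int pad, arma::mat& dW,
                    arma::vec& db, arma::cube* dx) {
  const int Cout = Wm.n_cols;
  arma::mat D(Cout, (size_t)ctx.Ho * ctx.Wo);
  for (int o = 0; o < Cout; ++o)
    D.row(o) = arma::vectorise(dy.slice(o)).t();
  db = arma::sum(D, 1);
  dW = ctx.cols * D.t();
  if (dx) {
    arma::mat dXcol = Wm * D;
    dx->zeros();
    col2im3(dXcol, pad, ctx.Ho, ctx.Wo, *dx);
  }
}

static arma::cube pool_fw(const arma::cube& x, arma::umat* argmax) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H < K || W < K) stop("input too small for 3x3 pooling");
  const int Ho = (H - K) / K + 1, Wo = (W - K) / K + 1;
  arma::cube y(Ho, Wo, C);
  if (argmax) argmax->set_size((size_t)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0, bj = 0;
        for (int dj = 0; dj < K; ++dj)
          for (int di = 0; di < K; ++di) {
            const double v = xs(K * i + di, K * j + dj);
            if (v > best) { best = v; bi = K * i + di; bj = K * j + dj; }
          }
        y(i, j, c) = best;
        if (argmax) (*argmax)((size_t)j * Ho + i, c) = bi + H * bj;
      }
    }
  }
  return y;
}

static arma::cube pool_bw(const arma::umat& argmax, const arma::cube& dy,
                          int H, int W) {
  const int C = dy.n_slices, Ho = dy.n_rows, Wo = dy.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dys = dy.slice(c).memptr();
    double* dxs = dx.slice(c).memptr();
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
      dxs[argmax(q, c)] += dys[q];
  }
  return dx;
}

// ---- thin wrappers (kept exported for unit-level verification) ----------

static arma::cube as_cube(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() == 2)
    return arma::cube(const_cast<double*>(a.begin()), d[0], d[1], 1, false);
  return arma::cube(const_cast<double*>(a.begin()), d[0], d[1], d[2], false);
}

static NumericVector cube_to_r(const arma::cube& x) {
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static arma::mat weight_mat(const NumericVector& w_) {
  IntegerVector wd = w_.attr("dim");
  return arma::mat(const_cast<double*>(w_.begin()), 9 * wd[2], wd[3], false);
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x_, NumericVector w_,
                             NumericVector b, int pad) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  if ((int)x.n_slices != wd[2]) stop("channel mismatch in conv2d");
  return cube_to_r(conv_fw(x, weight_mat(w_),
                           arma::vec(b.begin(), b.size()), pad, nullptr));
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x_, NumericVector w_, NumericVector dy_,
                     int pad) {
  arma::cube x = as_cube(x_);
  arma::cube dy = as_cube(dy_);
  IntegerVector wd = w_.attr("dim");
  arma::mat Wm = weight_mat(w_);
  ConvCtx ctx;
  ctx.Ho = dy.n_rows; ctx.Wo = dy.n_cols;
  ctx.cols = im2col3(x, pad, ctx.Ho, ctx.Wo);
  arma::mat dW; arma::vec db;
  arma::cube dx(x.n_rows, x.n_cols, x.n_slices);
  conv_bw(ctx, Wm, dy, pad, dW, db, &dx);
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(3, 3, wd[2], wd[3]);
  return List::create(_["dx"] = cube_to_r(dx), _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpoolForward")]]
List maxpool_forward(NumericVector x_) {
  arma::cube x = as_cube(x_);
  arma::umat am;
  arma::cube y = pool_fw(x, &am);
  const int H = x.n_rows, W = x.n_cols;
  IntegerVector idx(y.n_elem);
  for (size_t c = 0; c < y.n_slices; ++c)
    for (size_t q = 0; q < (size_t)y.n_rows * y.n_cols; ++q)
      idx[c * y.n_rows * y.n_cols + q] =
        (int)(am(q, c) + (size_t)H * W * c);
  idx.attr("dim") = IntegerVector::create(y.n_rows, y.n_cols, y.n_slices);
  return List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpoolBackward")]]
NumericVector maxpool_backward(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2]);
  const int n = idx.size();
  for (int k = 0; k < n; ++k) dx[idx[k]] += dy[k];
  dx.attr("dim") = xdim;
  return dx;
}

// ---- fused branch passes ------------------------------------------------

struct BranchW {
  arma::mat W1, W2, W3, A1;
  arma::vec b1, b2, b3, A1b;
  NumericVector w1r, w2r, w3r; // keep dims for gradient shaping
};

static BranchW branch_weights(const List& p) {
  BranchW w;
  NumericVector w1 = p["W1"], w2 = p["W2"], w3 = p["W3"];
  NumericVector b1 = p["b1"], b2 = p["b2"], b3 = p["b3"];
  NumericMatrix a1 = p["A1"];
  NumericVector a1b = p["A1b"];
  w.W1 = weight_mat(w1); w.W2 = weight_mat(w2); w.W3 = weight_mat(w3);
  w.b1 = arma::vec(b1.begin(), b1.size());
  w.b2 = arma::vec(b2.begin(), b2.size());
  w.b3 = arma::vec(b3.begin(), b3.size());
  w.A1 = arma::mat(a1.begin(), a1.nrow(), a1.ncol(), false);
  w.A1b = arma::vec(a1b.begin(), a1b.size());
  w.w1r = w1; w.w2r = w2; w.w3r = w3;
  return w;
}

struct BranchState {
  ConvCtx ctx1, ctx2, ctx3;
  arma::umat am1, am2, am3;
  arma::cube c1, p1, c2, p2, c3, p3;
  arma::vec f;
};

static arma::vec branch_fw(const arma::cube& x, const BranchW& w,
                           BranchState* st, BranchState& tmp) {
  BranchState& s = st ? *st : tmp;
  s.c1 = conv_fw(x, w.W1, w.b1, 1, st ? &s.ctx1 : nullptr);
  s.p1 = pool_fw(s.c1, st ? &s.am1 : nullptr);
  s.c2 = conv_fw(s.p1, w.W2, w.b2, 0, st ? &s.ctx2 : nullptr);
  s.p2 = pool_fw(s.c2, st ? &s.am2 : nullptr);
  s.c3 = conv_fw(s.p2, w.W3, w.b3, 0, st ? &s.ctx3 : nullptr);
  s.p3 = pool_fw(s.c3, st ? &s.am3 : nullptr);
  s.f = arma::vectorise(s.p3);
  return w.A1 * s.f + w.A1b;
}

// embedding-only forward: input matrix -> 20-vector
// [[Rcpp::export(name = ".branchEmbed")]]
NumericVector branch_embed(NumericMatrix x_, List params) {
  arma::cube x(x_.begin(), x_.nrow(), x_.ncol(), 1, false);
  BranchW w = branch_weights(params);
  BranchState tmp;
  arma::vec e = branch_fw(x, w, nullptr, tmp);
  return NumericVector(e.begin(), e.end());
}

// fused forward + backward: recomputes the branch forward pass with caches
// and backpropagates the embedding gradient; returns parameter gradients
// only (input gradients are not needed)
// [[Rcpp::export(name = ".branchGrads")]]
List branch_grads(NumericMatrix x_, List params, NumericVector de_) {
  arma::cube x(x_.begin(), x_.nrow(), x_.ncol(), 1, false);
  BranchW w = branch_weights(params);
  BranchState s, tmp;
  branch_fw(x, w, &s, tmp);
  arma::vec de(de_.begin(), de_.size());

  arma::mat dA1 = de * s.f.t();
  arma::vec df = w.A1.t() * de;
  arma::cube dp3(s.p3.n_rows, s.p3.n_cols, s.p3.n_slices);
  std::copy(df.begin(), df.end(), dp3.begin());
  arma::cube dc3 = pool_bw(s.am3, dp3, s.c3.n_rows, s.c3.n_cols);
  arma::mat dW3; arma::vec db3;
  arma::cube dp2(s.p2.n_rows, s.p2.n_cols, s.p2.n_slices);
  conv_bw(s.ctx3, w.W3, dc3, 0, dW3, db3, &dp2);
  arma::cube dc2 = pool_bw(s.am2, dp2, s.c2.n_rows, s.c2.n_cols);
  arma::mat dW2; arma::vec db2;
  arma::cube dp1(s.p1.n_rows, s.p1.n_cols, s.p1.n_slices);
  conv_bw(s.ctx2, w.W2, dc2, 0, dW2, db2, &dp1);
  arma::cube dc1 = pool_bw(s.am1, dp1, s.c1.n_rows, s.c1.n_cols);
  arma::mat dW1; arma::vec db1;
  conv_bw(s.ctx1, w.W1, dc1, 1, dW1, db1, nullptr);

  NumericVector dW1r(dW1.begin(), dW1.end());
  dW1r.attr("dim") = w.w1r.attr("dim");
  NumericVector dW2r(dW2.begin(), dW2.end());
  dW2r.attr("dim") = w.w2r.attr("dim");
  NumericVector dW3r(dW3.begin(), dW3.end());
  dW3r.attr("dim") = w.w3r.attr("dim");
  NumericMatrix dA1r(dA1.n_rows, dA1.n_cols, dA1.begin());
  return List::create(
    _["W1"] = dW1r, _["b1"] = NumericVector(db1.begin(), db1.end()),
    _["W2"] = dW2r, _["b2"] = NumericVector(db2.begin(), db2.end()),
    _["W3"] = dW3r, _["b3"] = NumericVector(db3.begin(), db3.end()),
    _["A1"] = dA1r, _["A1b"] = NumericVector(de.begin(), de.end()));
}
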