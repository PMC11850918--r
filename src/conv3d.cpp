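// Blocked im2col 3D convolution kernels. Arrays are channel-last, column-major:
// a feature map of C channels over a (D,H,W) grid is an R array dim c(D,H,W,C),
// voxel (d,h,w,c) at linear index d + D*(h + H*(w + W*c)) (0-based).
// Weights are matrices (kd*kh*kw*Cin) x Cout with kernel offsets fastest
// (kd, then kh, then kw, then input channel). Zero padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int BLOCK_TARGET = 16384; // target rows per im2col block

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Valid output-index range [lo, hi) along one axis for kernel offset kk:
// input index i = o*s - p + kk must lie in [0, n).
static inline void valid_range(int n, int s, int p, int kk, int o_count,
                               int &lo, int &hi) {
  lo = (p - kk + s - 1) / s;       // ceil((p - kk) / s)
  if (lo < 0) lo = 0;
  hi = (n - 1 - kk + p) / s + 1;   // floor((n-1-kk+p)/s) + 1
  if (hi > o_count) hi = o_count;
  if (hi < lo) hi = lo;
}

// Fill the im2col block for output w-planes [w0, w1); cols has
// (w1-w0)*oh*od rows. Column-by-column with contiguous run copies along od.
static void fill_cols(const double *x, int D, int H, int W, int C,
                      int kd, int kh, int kw, int sd, int sh, int sw,
                      int pd, int ph, int pw, int od, int oh, int ow,
                      int w0, int w1, arma::mat &cols) {
  const int slab = od * oh;
  int dlo, dhi;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)D * H * W * c;
    for (int ow_k = 0; ow_k < kw; ++ow_k)
      for (int oh_k = 0; oh_k < kh; ++oh_k)
        for (int od_k = 0; od_k < kd; ++od_k) {
          const int col = od_k + kd * (oh_k + kh * (ow_k + kw * c));
          double *dst0 = cols.colptr(col);
          valid_range(D, sd, pd, od_k, od, dlo, dhi);
          for (int wi = w0; wi < w1; ++wi) {
            const int iw = wi * sw - pw + ow_k;
            double *dslab = dst0 + (size_t)(wi - w0) * slab;
            if (iw < 0 || iw >= W) {
              std::fill(dslab, dslab + slab, 0.0);
              continue;
            }
            for (int hi_ = 0; hi_ < oh; ++hi_) {
              const int ih = hi_ * sh - ph + oh_k;
              double *dst = dslab + (size_t)hi_ * od;
              if (ih < 0 || ih >= H) {
                std::fill(dst, dst + od, 0.0);
                continue;
              }
              const double *base = xc + (size_t)D * (ih + (size_t)H * iw);
              if (dlo > 0) std::fill(dst, dst + dlo, 0.0);
              if (sd == 1) {
                const int i0 = dlo * sd - pd + od_k;
                std::copy(base + i0, base + i0 + (dhi - dlo), dst + dlo);
              } else {
                for (int oi = dlo; oi < dhi; ++oi)
                  dst[oi] = base[oi * sd - pd + od_k];
              }
              if (dhi < od) std::fill(dst + dhi, dst + od, 0.0);
            }
          }
        }
  }
}

// Scatter-add the gradient block (transpose of fill_cols).
static void scatter_cols(double *dx, int D, int H, int W, int C,
                         int kd, int kh, int kw, int sd, int sh, int sw,
                         int pd, int ph, int pw, int od, int oh, int ow,
                         int w0, int w1, const arma::mat &dcols) {
  const int slab = od * oh;
  int dlo, dhi;
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)D * H * W * c;
    for (int ow_k = 0; ow_k < kw; ++ow_k)
      for (int oh_k = 0; oh_k < kh; ++oh_k)
        for (int od_k = 0; od_k < kd; ++od_k) {
          const int col = od_k + kd * (oh_k + kh * (ow_k + kw * c));
          const double *src0 = dcols.colptr(col);
          valid_range(D, sd, pd, od_k, od, dlo, dhi);
          for (int wi = w0; wi < w1; ++wi) {
            const int iw = wi * sw - pw + ow_k;
            if (iw < 0 || iw >= W) continue;
            const double *sslab = src0 + (size_t)(wi - w0) * slab;
            for (int hi_ = 0; hi_ < oh; ++hi_) {
              const int ih = hi_ * sh - ph + oh_k;
              if (ih < 0 || ih >= H) continue;
              const double *src = sslab + (size_t)hi_ * od;
              double *base = xc + (size_t)D * (ih + (size_t)H * iw);
              if (sd == 1) {
                const int i0 = dlo * sd - pd + od_k;
                double *b = base + i0;
                for (int oi = dlo; oi < dhi; ++oi) b[oi - dlo] += src[oi];
              } else {
                for (int oi = dlo; oi < dhi; ++oi)
                  base[oi * sd - pd + od_k] += src[oi];
              }
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".conv3d_fw_cpp")]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector dims,
                            NumericMatrix Wm, NumericVector b,
                            IntegerVector kern, IntegerVector stride,
                            IntegerVector pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int kd = kern[0], kh = kern[1], kw = kern[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int od = out_dim(D, kd, sd, pd), oh = out_dim(H, kh, sh, ph),
            ow = out_dim(W, kw, sw, pw);
  const int N = od * oh * ow, K = kd * kh * kw * C, Cout = Wm.ncol();
  if (Wm.nrow() != K) stop("weight rows do not match kernel x channels");
  const int slab = od * oh;
  const int wstep = std::max(1, BLOCK_TARGET / slab);
  arma::mat Wa(Wm.begin(), K, Cout, false);
  NumericVector y((size_t)N * Cout);
  arma::mat Ya(y.begin(), N, Cout, false);
  arma::mat cols(std::min(ow, wstep) * slab, K);
  for (int w0 = 0; w0 < ow; w0 += wstep) {
    const int w1 = std::min(ow, w0 + wstep);
    if ((w1 - w0) * slab != (int)cols.n_rows) cols.set_size((w1 - w0) * slab, K);
    fill_cols(x.begin(), D, H, W, C, kd, kh, kw, sd, sh, sw, pd, ph, pw,
              od, oh, ow, w0, w1, cols);
    Ya.rows((size_t)w0 * slab, (size_t)w1 * slab - 1) = cols * Wa;
  }
  for (int c = 0; c < Cout; ++c) Ya.col(c) += b[c];
  y.attr("dim") = IntegerVector::create(od, oh, ow, Cout);
  return y;
}

// [[Rcpp::export(name = ".conv3d_bw_cpp")]]
List conv3d_bw_cpp(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                   NumericVector dy, IntegerVector kern, IntegerVector stride,
                   IntegerVector pad, bool need_dx) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int kd = kern[0], kh = kern[1], kw = kern[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int od = out_dim(D, kd, sd, pd), oh = out_dim(H, kh, sh, ph),
            ow = out_dim(W, kw, sw, pw);
  const int N = od * oh * ow, K = kd * kh * kw * C, Cout = Wm.ncol();
  const int slab = od * oh;
  const int wstep = std::max(1, BLOCK_TARGET / slab);
  arma::mat Wa(Wm.begin(), K, Cout, false);
  arma::mat dYa(dy.begin(), N, Cout, false);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db = arma::sum(dYa, 0);
  NumericVector dx((size_t)D * H * W * C);
  arma::mat cols(std::min(ow, wstep) * slab, K);
  for (int w0 = 0; w0 < ow; w0 += wstep) {
    const int w1 = std::min(ow, w0 + wstep);
    if ((w1 - w0) * slab != (int)cols.n_rows) cols.set_size((w1 - w0) * slab, K);
    fill_cols(x.begin(), D, H, W, C, kd, kh, kw, sd, sh, sw, pd, ph, pw,
              od, oh, ow, w0, w1, cols);
    const arma::mat dYb = dYa.rows((size_t)w0 * slab, (size_t)w1 * slab - 1);
    dW += cols.t() * dYb;
    if (need_dx) {
      arma::mat dcols = dYb * Wa.t();
      scatter_cols(dx.begin(), D, H, W, C, kd, kh, kw, sd, sh, sw, pd, ph, pw,
                   od, oh, ow, w0, w1, dcols);
    }
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db.t()),
                      _["dx"] = dx);
}

// Interval-extraction tokenisation: non-overlapping s x s x s cells, one token
// per cell, token features ordered kernel-offsets-fastest then channel
// (identical to the im2col column layout with k = stride = s, pad = 0).
// [[Rcpp::export(name = ".token_gather_cpp")]]
NumericMatrix token_gather_cpp(NumericVector x, IntegerVector dims, int s) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int od = D / s, oh = H / s, ow = W / s;
  const int N = od * oh * ow, K = s * s * s * C;
  NumericMatrix tok(N, K);
  arma::mat cols(tok.begin(), N, K, false);
  fill_cols(x.begin(), D, H, W, C, s, s, s, s, s, s, 0, 0, 0, od, oh, ow,
            0, ow, cols);
  return tok;
}

// Exact inverse of token_gather (cells do not overlap).
// [[Rcpp::export(name = ".token_scatter_cpp")]]
NumericVector token_scatter_cpp(NumericMatrix tok, IntegerVector odims, int s,
                                int C) {
  const int od = odims[0], oh = odims[1], ow = odims[2];
  const int D = od * s, H = oh * s, W = ow * s;
  NumericVector x((size_t)D * H * W * C);
  arma::mat cols(tok.begin(), tok.nrow(), tok.ncol(), false);
  scatter_cols(x.begin(), D, H, W, C, s, s, s, s, s, s, 0, 0, 0,
               od, oh, ow, 0, ow, cols);
  x.attr("dim") = IntegerVector::create(D, H, W, C);
  return x;
}
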