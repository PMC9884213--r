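// 3D convolution / pooling kernels for the volumetric classifier.
// Layout: a batch is a numeric array with dim (C, D, H, W, N), C fastest.
// Convolutions are 3x3x3, stride 1, zero padding 1 ("same"); weights are a
// (F x 27C) matrix whose column index is ((kd*3+kh)*3+kw)*C + c with
// kernel offsets kd,kh,kw in {0,1,2} ~ {-1,0,+1}.  GEMM via Armadillo.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* x, int C, int D, int H, int W,
                   arma::mat& col) {
  const int DHW = D * H * W;
  col.zeros(27 * C, DHW);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        const int oc = ((w * H) + h) * D + d;  // output voxel (column)
        double* dst = col.colptr(oc);
        for (int kw = 0; kw < 3; ++kw) {
          int ww = w + kw - 1;
          if (ww < 0 || ww >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            int hh = h + kh - 1;
            if (hh < 0 || hh >= H) continue;
            for (int kd = 0; kd < 3; ++kd) {
              int dd = d + kd - 1;
              if (dd < 0 || dd >= D) continue;
              const double* src = x + (size_t)C * (((size_t)ww * H + hh) * D + dd);
              double* out = dst + (size_t)(((kd * 3) + kh) * 3 + kw) * C;
              for (int c = 0; c < C; ++c) out[c] = src[c];
            }
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int C, int D, int H, int W,
                       double* x) {
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        const int oc = ((w * H) + h) * D + d;
        const double* src0 = col.colptr(oc);
        for (int kw = 0; kw < 3; ++kw) {
          int ww = w + kw - 1;
          if (ww < 0 || ww >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            int hh = h + kh - 1;
            if (hh < 0 || hh >= H) continue;
            for (int kd = 0; kd < 3; ++kd) {
              int dd = d + kd - 1;
              if (dd < 0 || dd >= D) continue;
              double* dst = x + (size_t)C * (((size_t)ww * H + hh) * D + dd);
              const double* src = src0 + (size_t)(((kd * 3) + kh) * 3 + kw) * C;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericMatrix wts, NumericVector bias) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int Fo = wts.nrow();
  const int DHW = D * H * W;
  NumericVector y((R_xlen_t)Fo * DHW * N);
  arma::mat wm(wts.begin(), Fo, wts.ncol(), false);
  arma::vec bv(bias.begin(), Fo, false);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * C * DHW, C, D, H, W, col);
    arma::mat out = wm * col;      // Fo x DHW
    out.each_col() += bv;
    std::copy(out.begin(), out.end(), y.begin() + (R_xlen_t)n * Fo * DHW);
  }
  y.attr("dim") = IntegerVector::create(Fo, D, H, W, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim, NumericMatrix wts,
                    NumericVector dy, bool need_dx) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int Fo = wts.nrow();
  const int DHW = D * H * W;
  arma::mat wm(wts.begin(), Fo, wts.ncol(), false);
  arma::mat dw(Fo, wts.ncol(), arma::fill::zeros);
  arma::vec db(Fo, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : 0);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * C * DHW, C, D, H, W, col);
    arma::mat dyn(dy.begin() + (R_xlen_t)n * Fo * DHW, Fo, DHW, false);
    dw += dyn * col.t();
    db += arma::sum(dyn, 1);
    if (need_dx) {
      arma::mat dcol = wm.t() * dyn;  // 27C x DHW
      col2im_add(dcol, C, D, H, W, dx.begin() + (R_xlen_t)n * C * DHW);
    }
  }
  NumericMatrix dwout(Fo, wts.ncol());
  std::copy(dw.begin(), dw.end(), dwout.begin());
  NumericVector dbout(Fo);
  std::copy(db.begin(), db.end(), dbout.begin());
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dw"] = dwout, _["db"] = dbout, _["dx"] = dx);
}

// 2x2x2 max pooling, stride 2.  Returns pooled values and 1-based argmax
// indices into the input vector (for the backward scatter).
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  if (D % 2 || H % 2 || W % 2)
    stop("pooling requires even spatial dimensions, got %dx%dx%d", D, H, W);
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)C * Do * Ho * Wo * N);
  NumericVector idx((R_xlen_t)C * Do * Ho * Wo * N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = (R_xlen_t)n * C * D * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d)
          for (int c = 0; c < C; ++c) {
            double best = R_NegInf;
            R_xlen_t bidx = 0;
            for (int dw2 = 0; dw2 < 2; ++dw2)
              for (int dh = 0; dh < 2; ++dh)
                for (int dd = 0; dd < 2; ++dd) {
                  R_xlen_t id = base + c +
                    (R_xlen_t)C * (((R_xlen_t)(2*w+dw2) * H + (2*h+dh)) * D + (2*d+dd));
                  if (x[id] > best) { best = x[id]; bidx = id; }
                }
            y[o] = best;
            idx[o] = (double)(bidx + 1);
            ++o;
          }
  }
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector dy, NumericVector idx,
                                IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[(R_xlen_t)idx[i] - 1] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}
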