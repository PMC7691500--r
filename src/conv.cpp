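// Convolution and max-pooling kernels for the feature extractor.
//
// Activations are stored column-major as 5-d arrays (H, W, D, N, C); 2-d
// images use D = 1 and a kernel depth of 1, so a single code path serves both
// dimensionalities. Convolutions are "same"-size with the kernel anchored at
// the top-left corner and implicit zero padding at the trailing edge of each
// spatial axis (a 2x2(x2) kernel therefore pads one plane on the right /
// bottom / back). The forward pass materialises an im2col matrix and uses a
// BLAS gemm; the backward pass reuses the same gather pattern.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Gather x (H, W, D, N, Cin) into M of size (H*W*D*N) x (KOFF*Cin), where
// column off + KOFF*ic holds x shifted by kernel offset `off` (zero padded).
// Offset order: oh fastest, then ow, then od.
arma::mat im2col(const double* x, const int H, const int W, const int D,
                 const int N, const int Cin, const int kh, const int kw,
                 const int kd) {
  const int KOFF = kh * kw * kd;
  const arma::uword rows = (arma::uword)H * W * D * N;
  arma::mat M(rows, (arma::uword)KOFF * Cin, arma::fill::zeros);
  const long planeHW = (long)H * W;
  const long volHWD = planeHW * D;
  for (int ic = 0; ic < Cin; ++ic) {
    const double* xc = x + (long)ic * volHWD * N;
    for (int od = 0; od < kd; ++od) {
      for (int ow = 0; ow < kw; ++ow) {
        for (int oh = 0; oh < kh; ++oh) {
          const int off = oh + kh * (ow + kw * od);
          double* col = M.colptr((arma::uword)off + (arma::uword)KOFF * ic);
          for (int n = 0; n < N; ++n) {
            const double* xn = xc + (long)n * volHWD;
            double* dn = col + (long)n * volHWD;
            for (int d = 0; d < D; ++d) {
              const int sd = d + od;
              if (sd >= D) continue;
              const double* xp = xn + (long)sd * planeHW;
              double* dp = dn + (long)d * planeHW;
              for (int w = 0; w < W; ++w) {
                const int sw = w + ow;
                if (sw >= W) continue;
                const double* xq = xp + (long)sw * H;
                double* dq = dp + (long)w * H;
                const int hmax = H - oh;
                for (int h = 0; h < hmax; ++h) dq[h] = xq[h + oh];
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add transpose of im2col: dM (H*W*D*N) x (KOFF*Cin) back into dx.
void col2im(const arma::mat& dM, double* dx, const int H, const int W,
            const int D, const int N, const int Cin, const int kh,
            const int kw, const int kd) {
  const int KOFF = kh * kw * kd;
  const long planeHW = (long)H * W;
  const long volHWD = planeHW * D;
  for (int ic = 0; ic < Cin; ++ic) {
    double* xc = dx + (long)ic * volHWD * N;
    for (int od = 0; od < kd; ++od) {
      for (int ow = 0; ow < kw; ++ow) {
        for (int oh = 0; oh < kh; ++oh) {
          const int off = oh + kh * (ow + kw * od);
          const double* col =
              dM.colptr((arma::uword)off + (arma::uword)KOFF * ic);
          for (int n = 0; n < N; ++n) {
            double* xn = xc + (long)n * volHWD;
            const double* dn = col + (long)n * volHWD;
            for (int d = 0; d < D; ++d) {
              const int sd = d + od;
              if (sd >= D) continue;
              double* xp = xn + (long)sd * planeHW;
              const double* dp = dn + (long)d * planeHW;
              for (int w = 0; w < W; ++w) {
                const int sw = w + ow;
                if (sw >= W) continue;
                double* xq = xp + (long)sw * H;
                const double* dq = dp + (long)w * H;
                const int hmax = H - oh;
                for (int h = 0; h < hmax; ++h) xq[h + oh] += dq[h];
              }
            }
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".convForward")]]
NumericVector convForward(NumericVector x, IntegerVector xdim,
                          NumericMatrix w, NumericVector b,
                          IntegerVector kdim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], N = xdim[3], Cin = xdim[4];
  const int kh = kdim[0], kw = kdim[1], kd = kdim[2];
  const int Cout = w.ncol();
  arma::mat M = im2col(x.begin(), H, W, D, N, Cin, kh, kw, kd);
  const arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false, true);
  arma::mat Y = M * Wm;
  Y.each_row() += arma::rowvec(b.begin(), Cout);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, D, N, Cout);
  return out;
}

// [[Rcpp::export(name = ".convBackward")]]
List convBackward(NumericVector x, IntegerVector xdim, NumericMatrix w,
                  IntegerVector kdim, NumericVector dy, bool needDx) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], N = xdim[3], Cin = xdim[4];
  const int kh = kdim[0], kw = kdim[1], kd = kdim[2];
  const int Cout = w.ncol();
  const arma::uword rows = (arma::uword)H * W * D * N;
  const arma::mat dYm(dy.begin(), rows, Cout, false, true);
  arma::mat M = im2col(x.begin(), H, W, D, N, Cin, kh, kw, kd);
  arma::mat dW = M.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  NumericMatrix dWout(dW.n_rows, dW.n_cols);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbOut(db.begin(), db.end());
  NumericVector dxOut;
  if (needDx) {
    const arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false, true);
    arma::mat dM = dYm * Wm.t();
    dxOut = NumericVector((R_xlen_t)rows * Cin);
    col2im(dM, dxOut.begin(), H, W, D, N, Cin, kh, kw, kd);
    dxOut.attr("dim") = IntegerVector::create(H, W, D, N, Cin);
  }
  return List::create(_["dw"] = dWout, _["db"] = dbOut, _["dx"] = dxOut);
}

// Max pooling with factor (ph, pw, pd); spatial dims must be divisible.
// Returns the pooled tensor and the 1-based linear index of each maximum in
// x (ties resolved to the first position in h-then-w-then-d scan order).
// [[Rcpp::export(name = ".poolForward")]]
List poolForward(NumericVector x, IntegerVector xdim, IntegerVector pdim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], N = xdim[3], C = xdim[4];
  const int ph = pdim[0], pw = pdim[1], pd = pdim[2];
  const int Ho = H / ph, Wo = W / pw, Do = D / pd;
  const long planeHW = (long)H * W;
  const long volHWD = planeHW * D;
  const R_xlen_t nOut = (R_xlen_t)Ho * Wo * Do * N * C;
  NumericVector y(nOut);
  NumericVector which(nOut);  // double to allow > 2^31 - 1 linear indices
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const long base = ((long)c * N + n) * volHWD;
      for (int d = 0; d < Do; ++d)
        for (int w = 0; w < Wo; ++w)
          for (int h = 0; h < Ho; ++h) {
            double best = R_NegInf;
            long bestIdx = -1;
            for (int dd = 0; dd < pd; ++dd)
              for (int ww = 0; ww < pw; ++ww)
                for (int hh = 0; hh < ph; ++hh) {
                  const long idx = base + (long)(d * pd + dd) * planeHW +
                                   (long)(w * pw + ww) * H + (h * ph + hh);
                  if (xp[idx] > best) {
                    best = xp[idx];
                    bestIdx = idx;
                  }
                }
            y[o] = best;
            which[o] = (double)(bestIdx + 1);
            ++o;
          }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, N, C);
  return List::create(_["y"] = y, _["which"] = which);
}

// Fused ReLU + batch-norm forward over (M x C) activations (M = spatial x
// batch). Returns the normalised output, the rectified input (needed by the
// backward pass) and the batch mean / inverse-std per channel. In eval mode
// the provided running statistics are used instead.
// [[Rcpp::export(name = ".reluBnForward")]]
List reluBnForward(NumericVector x, IntegerVector xdim, NumericVector gamma,
                   NumericVector beta, NumericVector rmean,
                   NumericVector rvar, bool train, double eps) {
  const int C = xdim[4];
  const R_xlen_t M = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector y(M * C), r(M * C), mu(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    double* rc = r.begin() + M * c;
    double m = 0.0;
    for (R_xlen_t i = 0; i < M; ++i) {
      rc[i] = xc[i] > 0 ? xc[i] : 0.0;
      m += rc[i];
    }
    m /= M;
    double v = 0.0;
    if (train) {
      for (R_xlen_t i = 0; i < M; ++i) {
        const double d = rc[i] - m;
        v += d * d;
      }
      v /= M;
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    double batchMean = 0.0;
    if (train) {
      // batch mean of the rectified input, for the running-stat update
      batchMean = m;
    }
    mu[c] = train ? batchMean : m;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* yc = y.begin() + M * c;
    for (R_xlen_t i = 0; i < M; ++i) yc[i] = g * ((rc[i] - m) * is) + b;
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["r"] = r, _["mu"] = mu,
                      _["istd"] = istd);
}

// Fused backward of batch-norm + ReLU. `train` selects the full batch-norm
// Jacobian (batch statistics) versus the frozen running-statistic scaling.
// [[Rcpp::export(name = ".reluBnBackward")]]
List reluBnBackward(NumericVector dy, NumericVector r, IntegerVector xdim,
                    NumericVector gamma, NumericVector mu,
                    NumericVector istd, bool train) {
  const int C = xdim[4];
  const R_xlen_t M = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(M * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + M * c;
    const double* rc = r.begin() + M * c;
    double* dxc = dx.begin() + M * c;
    const double m = mu[c], is = istd[c], g = gamma[c];
    double sdy = 0.0, sdyx = 0.0;
    for (R_xlen_t i = 0; i < M; ++i) {
      const double xhat = (rc[i] - m) * is;
      sdy += dyc[i];
      sdyx += dyc[i] * xhat;
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    if (train) {
      const double mdx = g * sdy / M;      // mean of dxhat
      const double mdxx = g * sdyx / M;    // mean of dxhat * xhat
      for (R_xlen_t i = 0; i < M; ++i) {
        const double xhat = (rc[i] - m) * is;
        const double dr = is * (g * dyc[i] - mdx - xhat * mdxx);
        dxc[i] = rc[i] > 0 ? dr : 0.0;
      }
    } else {
      const double s = g * is;
      for (R_xlen_t i = 0; i < M; ++i)
        dxc[i] = rc[i] > 0 ? s * dyc[i] : 0.0;
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Scatter pooled gradients back to the pre-pooling shape.
// [[Rcpp::export(name = ".poolBackward")]]
NumericVector poolBackward(NumericVector dy, NumericVector which,
                           R_xlen_t nIn) {
  NumericVector dx(nIn);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i)
    dx[(R_xlen_t)which[i] - 1] += dy[i];
  return dx;
}
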