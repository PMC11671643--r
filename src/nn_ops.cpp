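// Low-level numerical kernels for the noise-prediction network.
// Convolutions are im2col + GEMM; gradients recompute the column matrix
// rather than caching it (memory stays flat across deep call stacks).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// col: (Ho*Wo) x (k*k*Cin), column index q = c*k*k + kj*k + ki,
// row index column-major over the output grid (matches R array layout).
static mat im2col(const cube& x, int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(static_cast<uword>(Ho) * Wo, static_cast<uword>(k) * k * C,
          fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword q = static_cast<uword>(c) * k * k + kj * k + ki;
        double* cq = col.colptr(q);
        // valid output-row range for this kernel offset
        int ilo = 0, ihi = Ho - 1;
        while (ilo * stride + ki - pad < 0) ++ilo;
        while (ihi * stride + ki - pad >= H) --ihi;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          const double* src = xc + static_cast<size_t>(xj) * H;
          double* dst = cq + static_cast<size_t>(j) * Ho;
          if (stride == 1) {
            const int n = ihi - ilo + 1;
            if (n > 0)
              std::memcpy(dst + ilo, src + (ilo + ki - pad),
                          n * sizeof(double));
          } else {
            for (int i = ilo; i <= ihi; ++i)
              dst[i] = src[i * stride + ki - pad];
          }
        }
      }
    }
  }
  return col;
}

// Wrap an R array as an Armadillo cube without copying.
static cube borrow_cube(const Rcpp::NumericVector& v) {
  Rcpp::IntegerVector d = v.attr("dim");
  return cube(const_cast<double*>(v.begin()), d[0], d[1], d[2], false, true);
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd(const Rcpp::NumericVector& x_,
                               const arma::mat& K, const arma::vec& b,
                               int k, int stride, int pad) {
  const cube x = borrow_cube(x_);
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = K.n_cols;
  mat col = im2col(x, k, stride, pad, Ho, Wo);
  Rcpp::NumericVector out_(static_cast<R_xlen_t>(Ho) * Wo * Cout);
  mat y(out_.begin(), static_cast<uword>(Ho) * Wo, Cout, false, true);
  y = col * K;
  y.each_row() += b.t();
  out_.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout);
  return out_;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const Rcpp::NumericVector& x_, const arma::mat& K,
                      const Rcpp::NumericVector& dy_, int k, int stride,
                      int pad) {
  const cube x = borrow_cube(x_);
  const cube dy = borrow_cube(dy_);
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const mat dyM(const_cast<double*>(dy.memptr()),
                static_cast<uword>(Ho) * Wo, Cout, false, true);
  mat col = im2col(x, k, stride, pad, Ho, Wo);
  mat dK = col.t() * dyM;
  vec db = sum(dyM, 0).t();
  mat dcol = dyM * K.t();
  cube dx(H, W, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* dxc = dx.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword q = static_cast<uword>(c) * k * k + kj * k + ki;
        const double* cq = dcol.colptr(q);
        int ilo = 0, ihi = Ho - 1;
        while (ilo * stride + ki - pad < 0) ++ilo;
        while (ihi * stride + ki - pad >= H) --ihi;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          double* dst = dxc + static_cast<size_t>(xj) * H + (ki - pad);
          const double* src = cq + static_cast<size_t>(j) * Ho;
          for (int i = ilo; i <= ihi; ++i)
            dst[i * stride] += src[i];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dK,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::NumericVector silu_fwd(const Rcpp::NumericVector& x_) {
  Rcpp::NumericVector y(x_.size());
  const double* x = x_.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x_.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    yp[i] = x[i] * s;
  }
  y.attr("dim") = x_.attr("dim");
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector silu_bwd(const Rcpp::NumericVector& x_,
                             const Rcpp::NumericVector& dy_) {
  Rcpp::NumericVector dx(x_.size());
  const double* x = x_.begin();
  const double* dy = dy_.begin();
  double* d = dx.begin();
  for (R_xlen_t i = 0; i < x_.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    d[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  dx.attr("dim") = x_.attr("dim");
  return dx;
}

// Group normalization over an (H, W, C) array with channels grouped
// contiguously; returns y plus the normalized values and inverse standard
// deviations needed by the backward pass.
// [[Rcpp::export]]
Rcpp::List gn_fwd(const Rcpp::NumericVector& x_, const arma::vec& gamma,
                  const arma::vec& beta, int ngroups) {
  Rcpp::IntegerVector d = x_.attr("dim");
  const uword HW = static_cast<uword>(d[0]) * d[1];
  const uword C = d[2];
  const uword N = HW * C / ngroups;
  const mat Xg(const_cast<double*>(x_.begin()), N, ngroups, false, true);
  vec invstd(ngroups);
  Rcpp::NumericVector xhat_(x_.size());
  mat Hg(xhat_.begin(), N, ngroups, false, true);
  for (int g = 0; g < ngroups; ++g) {
    const double mu = arma::mean(Xg.col(g));
    vec xc = Xg.col(g) - mu;
    const double v = arma::dot(xc, xc) / N;
    invstd(g) = 1.0 / std::sqrt(v + 1e-5);
    Hg.col(g) = xc * invstd(g);
  }
  Rcpp::NumericVector y_(x_.size());
  mat Y(y_.begin(), HW, C, false, true);
  const mat Hm(xhat_.begin(), HW, C, false, true);
  for (uword c = 0; c < C; ++c)
    Y.col(c) = Hm.col(c) * gamma(c) + beta(c);
  y_.attr("dim") = x_.attr("dim");
  return Rcpp::List::create(Rcpp::Named("y") = y_,
                            Rcpp::Named("xhat") = xhat_,
                            Rcpp::Named("invstd") = invstd);
}

// [[Rcpp::export]]
Rcpp::List gn_bwd(const Rcpp::NumericVector& dy_,
                  const Rcpp::NumericVector& xhat_, const arma::vec& invstd,
                  const arma::vec& gamma, int ngroups) {
  Rcpp::IntegerVector d = dy_.attr("dim");
  const uword HW = static_cast<uword>(d[0]) * d[1];
  const uword C = d[2];
  const uword N = HW * C / ngroups;
  const uword Cg = C / ngroups;
  const mat dyM(const_cast<double*>(dy_.begin()), HW, C, false, true);
  const mat Hm(const_cast<double*>(xhat_.begin()), HW, C, false, true);
  vec dgamma(C), dbeta(C);
  Rcpp::NumericVector dxh_(dy_.size());
  mat DxhM(dxh_.begin(), HW, C, false, true);
  for (uword c = 0; c < C; ++c) {
    dgamma(c) = arma::dot(dyM.col(c), Hm.col(c));
    dbeta(c) = arma::accu(dyM.col(c));
    DxhM.col(c) = dyM.col(c) * gamma(c);
  }
  mat Dg(dxh_.begin(), N, ngroups, false, true);
  const mat Hg(const_cast<double*>(xhat_.begin()), N, ngroups, false, true);
  Rcpp::NumericVector dx_(dy_.size());
  mat Dx(dx_.begin(), N, ngroups, false, true);
  for (int g = 0; g < ngroups; ++g) {
    const double s1 = arma::accu(Dg.col(g)) / N;
    const double s2 = arma::dot(Dg.col(g), Hg.col(g)) / N;
    Dx.col(g) = (Dg.col(g) - s1 - Hg.col(g) * s2) * invstd(g);
  }
  dx_.attr("dim") = dy_.attr("dim");
  return Rcpp::List::create(Rcpp::Named("dx") = dx_,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Training-path forward that also returns the column matrix so the backward
// pass can skip recomputing im2col.
// [[Rcpp::export]]
Rcpp::List conv2d_fwd_train(const Rcpp::NumericVector& x_, const arma::mat& K,
                            const arma::vec& b, int k, int stride, int pad) {
  const cube x = borrow_cube(x_);
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = K.n_cols;
  mat col = im2col(x, k, stride, pad, Ho, Wo);
  Rcpp::NumericVector out_(static_cast<R_xlen_t>(Ho) * Wo * Cout);
  mat y(out_.begin(), static_cast<uword>(Ho) * Wo, Cout, false, true);
  y = col * K;
  y.each_row() += b.t();
  out_.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout);
  return Rcpp::List::create(Rcpp::Named("y") = out_,
                            Rcpp::Named("col") = col);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cached(const arma::mat& col,
                             const Rcpp::IntegerVector& xdim,
                             const arma::mat& K,
                             const Rcpp::NumericVector& dy_, int k,
                             int stride, int pad) {
  const cube dy = borrow_cube(dy_);
  const int H = xdim[0], W = xdim[1], Cin = xdim[2];
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const mat dyM(const_cast<double*>(dy.memptr()),
                static_cast<uword>(Ho) * Wo, Cout, false, true);
  mat dK = col.t() * dyM;
  vec db = sum(dyM, 0).t();
  mat dcol = dyM * K.t();
  cube dx(H, W, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* dxc = dx.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const uword q = static_cast<uword>(c) * k * k + kj * k + ki;
        const double* cq = dcol.colptr(q);
        int ilo = 0, ihi = Ho - 1;
        while (ilo * stride + ki - pad < 0) ++ilo;
        while (ihi * stride + ki - pad >= H) --ihi;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          double* dst = dxc + static_cast<size_t>(xj) * H + (ki - pad);
          const double* src = cq + static_cast<size_t>(j) * Ho;
          for (int i = ilo; i <= ihi; ++i)
            dst[i * stride] += src[i];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dK,
                            Rcpp::Named("db") = db);
}
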