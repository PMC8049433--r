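// Hot loops of the 1-D convolutional layers: "same"-padded convolution
// (forward, backward-data, backward-filter), max-pooling and nearest
// upsampling on (batch x length x channels) arrays stored column-major
// with the batch index fastest. Because the batch index is fastest, a
// time shift by s samples is a row offset of s*n in the flattened
// (n*L x C) view and never crosses a batch boundary, so each kernel tap
// is one BLAS dgemm on a pointer-offset submatrix — no im2col copy. The
// R level keeps the dense/batch-norm algebra and all bookkeeping;
// equivalence with a direct R implementation is asserted in the test
// suite.
#include <Rcpp.h>
#include <algorithm>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// y[i,t,co] = b[co] + sum_{j,ci} x[i, t + j - pad, ci] * W[j*C + ci, co]
// [[Rcpp::export]]
NumericVector conv1d_fwd(NumericVector x, NumericMatrix W, NumericVector b,
                         int n, int L, int C, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const int nL = n * L;
  NumericVector y((R_xlen_t)nL * Cout);
  const double *px = REAL(x);
  const double *pW = REAL(W);
  double *py = REAL(y);
  for (int co = 0; co < Cout; ++co) {
    std::fill(py + (R_xlen_t)co * nL, py + (R_xlen_t)(co + 1) * nL, b[co]);
  }
  const int ldw = k * C;
  const double one = 1.0;
  for (int j = 0; j < k; ++j) {
    const int s = j - pad;
    const int t0 = std::max(0, -s);          // first valid output time
    const int len = L - std::abs(s);         // valid output times
    if (len <= 0 || C == 0) continue;
    const int m = len * n;
    // y[t0.., ] += x[(t0+s).., ] %*% W[jC..jC+C-1, ]
    F77_CALL(dgemm)("N", "N", &m, &Cout, &C, &one,
                    px + (R_xlen_t)(t0 + s) * n, &nL,
                    pW + j * C, &ldw, &one,
                    py + (R_xlen_t)t0 * n, &nL FCONE FCONE);
  }
  y.attr("dim") = IntegerVector::create(n, L, Cout);
  return y;
}

// dx[i,t,ci] = sum_{j,co} dy[i, t - (j - pad), co] * W[j*C + ci, co]
// [[Rcpp::export]]
NumericVector conv1d_bwd_data(NumericVector dy, NumericMatrix W,
                              int n, int L, int C, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const int nL = n * L;
  NumericVector dx((R_xlen_t)nL * C);  // zero-initialized
  const double *pdy = REAL(dy);
  const double *pW = REAL(W);
  double *pdx = REAL(dx);
  const int ldw = k * C;
  const double one = 1.0;
  for (int j = 0; j < k; ++j) {
    const int s = j - pad;
    const int t0 = std::max(0, s);           // first valid input time
    const int len = L - std::abs(s);
    if (len <= 0 || Cout == 0) continue;
    const int m = len * n;
    // dx[t0.., ] += dy[(t0-s).., ] %*% t(W[jC..jC+C-1, ])
    F77_CALL(dgemm)("N", "T", &m, &C, &Cout, &one,
                    pdy + (R_xlen_t)(t0 - s) * n, &nL,
                    pW + j * C, &ldw, &one,
                    pdx + (R_xlen_t)t0 * n, &nL FCONE FCONE);
  }
  dx.attr("dim") = IntegerVector::create(n, L, C);
  return dx;
}

// dW[j*C + ci, co] = sum_{i,t} x[i, t + j - pad, ci] * dy[i, t, co]
// [[Rcpp::export]]
NumericMatrix conv1d_bwd_filter(NumericVector x, NumericVector dy,
                                int n, int L, int C, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const int nL = n * L;
  NumericMatrix dW(k * C, Cout);  // zero-initialized
  const double *px = REAL(x), *pdy = REAL(dy);
  double *pdW = REAL(dW);
  const int ldw = k * C;
  const double one = 1.0, zero = 0.0;
  for (int j = 0; j < k; ++j) {
    const int s = j - pad;
    const int t0 = std::max(0, -s);
    const int m = L - std::abs(s);
    if (m <= 0) continue;
    const int mk = m * n;
    // dW[jC..jC+C-1, ] = t(x[(t0+s).., ]) %*% dy[t0.., ]
    F77_CALL(dgemm)("T", "N", &C, &Cout, &mk, &one,
                    px + (R_xlen_t)(t0 + s) * n, &nL,
                    pdy + (R_xlen_t)t0 * n, &nL, &zero,
                    pdW + j * C, &ldw FCONE FCONE);
  }
  return dW;
}

// Max-pooling by `f` along the length axis; `arg` records the winning
// within-window offset (1-based, first maximum wins on ties).
// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int n, int L, int C, int f) {
  const int Lo = L / f;
  NumericVector y((R_xlen_t)n * Lo * C);
  IntegerVector arg((R_xlen_t)n * Lo * C);
  const double *px = REAL(x);
  double *py = REAL(y);
  int *pa = INTEGER(arg);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lo; ++t) {
      const double *x0 = px + ((R_xlen_t)c * L + (R_xlen_t)t * f) * n;
      double *yt = py + ((R_xlen_t)c * Lo + t) * n;
      int *at = pa + ((R_xlen_t)c * Lo + t) * n;
      for (int i = 0; i < n; ++i) { yt[i] = x0[i]; at[i] = 1; }
      for (int j = 1; j < f; ++j) {
        const double *xj = x0 + (R_xlen_t)j * n;
        for (int i = 0; i < n; ++i) {
          if (xj[i] > yt[i]) { yt[i] = xj[i]; at[i] = j + 1; }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(n, Lo, C);
  arg.attr("dim") = IntegerVector::create(n, Lo, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector arg,
                          int n, int L, int C, int f) {
  const int Lo = L / f;
  NumericVector dx((R_xlen_t)n * L * C);
  const double *pdy = REAL(dy);
  const int *pa = INTEGER(arg);
  double *pdx = REAL(dx);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lo; ++t) {
      const double *dyt = pdy + ((R_xlen_t)c * Lo + t) * n;
      const int *at = pa + ((R_xlen_t)c * Lo + t) * n;
      double *x0 = pdx + ((R_xlen_t)c * L + (R_xlen_t)t * f) * n;
      for (int i = 0; i < n; ++i) x0[i + (R_xlen_t)(at[i] - 1) * n] = dyt[i];
    }
  }
  dx.attr("dim") = IntegerVector::create(n, L, C);
  return dx;
}

// Nearest-neighbour upsampling by `f` along the length axis.
// [[Rcpp::export]]
NumericVector upsample_fwd(NumericVector x, int n, int L, int C, int f) {
  NumericVector y((R_xlen_t)n * L * f * C);
  const double *px = REAL(x);
  double *py = REAL(y);
  const int Lo = L * f;
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < L; ++t) {
      const double *xt = px + ((R_xlen_t)c * L + t) * n;
      for (int j = 0; j < f; ++j) {
        double *yt = py + ((R_xlen_t)c * Lo + (R_xlen_t)t * f + j) * n;
        std::copy(xt, xt + n, yt);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(n, Lo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_bwd(NumericVector dy, int n, int L, int C, int f) {
  NumericVector dx((R_xlen_t)n * L * C);
  const double *pdy = REAL(dy);
  double *pdx = REAL(dx);
  const int Lo = L * f;
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < L; ++t) {
      double *dxt = pdx + ((R_xlen_t)c * L + t) * n;
      for (int j = 0; j < f; ++j) {
        const double *dyt = pdy + ((R_xlen_t)c * Lo + (R_xlen_t)t * f + j) * n;
        for (int i = 0; i < n; ++i) dxt[i] += dyt[i];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(n, L, C);
  return dx;
}

// Fused batch-norm training forward over the columns of an (m x p) matrix:
// one pass for the moments, one for the normalized output.
// [[Rcpp::export]]
List bn_train_fwd(NumericMatrix x, NumericVector gamma, NumericVector beta,
                  double eps) {
  const int m = x.nrow(), p = x.ncol();
  NumericMatrix y(m, p), xhat(m, p);
  NumericVector mu(p), var(p), invstd(p);
  for (int c = 0; c < p; ++c) {
    const double *xc = &x(0, c);
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < m; ++i) { s += xc[i]; ss += xc[i] * xc[i]; }
    const double mean = s / m;
    const double v = ss / m - mean * mean;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = mean; var[c] = v; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double *xh = &xhat(0, c), *yc = &y(0, c);
    for (int i = 0; i < m; ++i) {
      const double h = (xc[i] - mean) * is;
      xh[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// Batch-norm backward: dx = invstd * (dxhat - mean(dxhat) - xhat*mean(dxhat*xhat))
// with dxhat = dy * gamma, plus the parameter gradients.
// [[Rcpp::export]]
List bn_train_bwd(NumericMatrix dy, NumericMatrix xhat, NumericVector gamma,
                  NumericVector invstd) {
  const int m = dy.nrow(), p = dy.ncol();
  NumericMatrix dx(m, p);
  NumericVector dgamma(p), dbeta(p);
  for (int c = 0; c < p; ++c) {
    const double *dyc = &dy(0, c), *xh = &xhat(0, c);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < m; ++i) {
      s1 += dyc[i];
      s2 += dyc[i] * xh[i];
    }
    dbeta[c] = s1; dgamma[c] = s2;
    const double g = gamma[c], is = invstd[c];
    const double m1 = g * s1 / m, m2 = g * s2 / m;
    double *dxc = &dx(0, c);
    for (int i = 0; i < m; ++i) {
      dxc[i] = is * (g * dyc[i] - m1 - xh[i] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double *px = REAL(x);
  double *py = REAL(y);
  const R_xlen_t nn = x.size();
  for (R_xlen_t i = 0; i < nn; ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// Backward through ReLU using the cached output (y > 0 <=> x > 0).
// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double *pdy = REAL(dy), *py = REAL(y);
  double *pdx = REAL(dx);
  const R_xlen_t nn = dy.size();
  for (R_xlen_t i = 0; i < nn; ++i) pdx[i] = py[i] > 0 ? pdy[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
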