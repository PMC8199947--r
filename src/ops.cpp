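// Low-level array kernels for the segmentation network and the deep-feature
// backbone: cross-correlation style convolution (im2col + GEMM), max pooling
// with argmax bookkeeping, the adjoint (col2im) used both for convolution
// input-gradients and transposed-convolution forward passes, and an
// 8-connected component labeller for binary masks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int s, int p) {
  return (H + 2 * p - k) / s + 1;
}

static void dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

static inline int ceil_div(int a, int s) {
  return a > 0 ? (a + s - 1) / s : a / s;
}
static inline int floor_div(int a, int s) {
  return a >= 0 ? a / s : -((-a + s - 1) / s);
}

// Gather sliding k x k windows of x (H,W,C,N) into a matrix with
// rows indexed by (oh, ow, n) and columns by (kh, kw, c). Bounds are
// hoisted out of the inner loops; stride-1 rows copy with memcpy.
static arma::mat im2col(const double *x, int H, int W, int C, int N,
                        int k, int s, int p, int Ho, int Wo) {
  const arma::uword rows = (arma::uword)N * Ho * Wo;
  arma::mat col(rows, (arma::uword)k * k * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double *xc = xn + (size_t)H * W * c;
      for (int kw = 0; kw < k; ++kw) {
        const int owLo = std::max(0, ceil_div(p - kw, s));
        const int owHi = std::min(Wo - 1, floor_div(W - 1 + p - kw, s));
        for (int kh = 0; kh < k; ++kh) {
          const int ohLo = std::max(0, ceil_div(p - kh, s));
          const int ohHi = std::min(Ho - 1, floor_div(H - 1 + p - kh, s));
          if (ohHi < ohLo || owHi < owLo) continue;
          const arma::uword j = (arma::uword)kh + k * kw + (arma::uword)k * k * c;
          double *dst = col.colptr(j) + (arma::uword)Ho * Wo * n;
          for (int ow = owLo; ow <= owHi; ++ow) {
            const int iw = ow * s - p + kw;
            const double *src = xc + (size_t)H * iw;
            double *d2 = dst + (size_t)Ho * ow;
            if (s == 1) {
              std::memcpy(d2 + ohLo, src + (ohLo - p + kh),
                          (size_t)(ohHi - ohLo + 1) * sizeof(double));
            } else {
              for (int oh = ohLo; oh <= ohHi; ++oh)
                d2[oh] = src[oh * s - p + kh];
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add the adjoint of im2col.
static void col2im(const arma::mat &D, double *gx, int H, int W, int C, int N,
                   int k, int s, int p, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double *gn = gx + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      double *gc = gn + (size_t)H * W * c;
      for (int kw = 0; kw < k; ++kw) {
        const int owLo = std::max(0, ceil_div(p - kw, s));
        const int owHi = std::min(Wo - 1, floor_div(W - 1 + p - kw, s));
        for (int kh = 0; kh < k; ++kh) {
          const int ohLo = std::max(0, ceil_div(p - kh, s));
          const int ohHi = std::min(Ho - 1, floor_div(H - 1 + p - kh, s));
          if (ohHi < ohLo || owHi < owLo) continue;
          const arma::uword j = (arma::uword)kh + k * kw + (arma::uword)k * k * c;
          const double *src = D.colptr(j) + (arma::uword)Ho * Wo * n;
          for (int ow = owLo; ow <= owHi; ++ow) {
            const int iw = ow * s - p + kw;
            double *d2 = gc + (size_t)H * iw;
            const double *s2 = src + (size_t)Ho * ow;
            if (s == 1) {
              double *dd = d2 + (ohLo - p + kh);
              const double *ss = s2 + ohLo;
              const int len = ohHi - ohLo + 1;
              for (int t = 0; t < len; ++t) dd[t] += ss[t];
            } else {
              for (int oh = ohLo; oh <= ohHi; ++oh)
                d2[oh * s - p + kh] += s2[oh];
            }
          }
        }
      }
    }
  }
}

// Reshape (Ho,Wo,F,N) array into the (oh,ow,n) x F matrix used by GEMM.
static arma::mat to_rows(const double *y, int Ho, int Wo, int F, int N) {
  arma::mat G((arma::uword)N * Ho * Wo, F);
  const size_t plane = (size_t)Ho * Wo;
  for (int f = 0; f < F; ++f)
    for (int n = 0; n < N; ++n)
      std::memcpy(G.colptr(f) + plane * n, y + plane * (f + (size_t)F * n),
                  plane * sizeof(double));
  return G;
}

static void from_rows(const arma::mat &Y, double *y, int Ho, int Wo, int F, int N) {
  const size_t plane = (size_t)Ho * Wo;
  for (int f = 0; f < (int)Y.n_cols; ++f)
    for (int n = 0; n < N; ++n)
      std::memcpy(y + plane * (f + (size_t)F * n), Y.colptr(f) + plane * n,
                  plane * sizeof(double));
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, const arma::mat &W,
                           const arma::vec &b, int k, int s, int p) {
  int d[4]; dims4(x, d);
  const int H = d[0], Wd = d[1], C = d[2], N = d[3];
  if ((int)W.n_rows != k * k * C) stop("weight rows != k*k*C");
  const int F = W.n_cols;
  const int Ho = out_dim(H, k, s, p), Wo = out_dim(Wd, k, s, p);
  if (Ho < 1 || Wo < 1) stop("convolution output dimension underflow");
  arma::mat col = im2col(REAL(x), H, Wd, C, N, k, s, p, Ho, Wo);
  arma::mat Y = col * W;
  Y.each_row() += b.t();
  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  from_rows(Y, REAL(y), Ho, Wo, F, N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_input(NumericVector gy, const arma::mat &W,
                                 int k, int s, int p, int H, int Win) {
  int d[4]; dims4(gy, d);
  const int Ho = d[0], Wo = d[1], F = d[2], N = d[3];
  if ((int)W.n_cols != F) stop("weight cols != output channels");
  const int C = W.n_rows / (k * k);
  arma::mat G = to_rows(REAL(gy), Ho, Wo, F, N);
  arma::mat D = G * W.t();
  NumericVector gx((R_xlen_t)H * Win * C * N);
  col2im(D, REAL(gx), H, Win, C, N, k, s, p, Ho, Wo);
  gx.attr("dim") = IntegerVector::create(H, Win, C, N);
  return gx;
}

// [[Rcpp::export]]
List cpp_conv_gradw(NumericVector x, NumericVector gy, int k, int s, int p) {
  int d[4]; dims4(x, d);
  const int H = d[0], Wd = d[1], C = d[2], N = d[3];
  int dg[4]; dims4(gy, dg);
  const int Ho = dg[0], Wo = dg[1], F = dg[2];
  if (dg[3] != N) stop("batch mismatch");
  if (Ho != out_dim(H, k, s, p) || Wo != out_dim(Wd, k, s, p))
    stop("gradient spatial dims inconsistent with convolution geometry");
  arma::mat col = im2col(REAL(x), H, Wd, C, N, k, s, p, Ho, Wo);
  arma::mat G = to_rows(REAL(gy), Ho, Wo, F, N);
  arma::mat gW = col.t() * G;
  arma::rowvec gb = arma::sum(G, 0);
  return List::create(_["gW"] = gW, _["gb"] = arma::vec(gb.t()));
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int size, int stride) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = out_dim(H, size, stride, 0), Wo = out_dim(W, size, stride, 0);
  if (Ho < 1 || Wo < 1) stop("pooling output dimension underflow");
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  int *ip = INTEGER(idx);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -INFINITY; size_t bi = 0;
          for (int kw = 0; kw < size; ++kw)
            for (int kh = 0; kh < size; ++kh) {
              const size_t li = base + (size_t)H * (ow * stride + kw) +
                                (oh * stride + kh);
              if (xp[li] > best) { best = xp[li]; bi = li; }
            }
          // column-major output: oh fastest, then ow, then (c, n)
          const R_xlen_t oo = (R_xlen_t)oh + Ho * ow +
            (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
          yp[oo] = best; ip[oo] = (int)bi;
          ++o;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx,
                              int H, int W) {
  int d[4]; dims4(gy, d);
  const int C = d[2], N = d[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  double *gp = REAL(gx);
  const double *gyp = REAL(gy);
  const int *ip = INTEGER(idx);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gp[ip[i]] += gyp[i];
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// 8-connected component labelling of a binary matrix (BFS flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int v = stack.back(); stack.pop_back();
        const int vi = v % H, vj = v / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ni = vi + di, nj = vj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + H * nj);
            }
          }
      }
    }
  return lab;
}

// In-place C += alpha * t(A) %*% B via a direct BLAS dgemm call with
// beta = 1 (no temporaries); used for the large fully connected weight
// updates where an R-level or expression-template update would allocate
// an 800 MB intermediate per step.
// [[Rcpp::export]]
void cpp_gemm_tn_update(NumericMatrix C, const NumericMatrix &A,
                        const NumericMatrix &B, double alpha) {
  const arma::blas_int m = A.ncol(), n = B.ncol(), k = A.nrow();
  if (C.nrow() != m || C.ncol() != n || B.nrow() != k)
    stop("dimension mismatch in gemm update");
  const double beta = 1.0;
  const char tA = 'T', tB = 'N';
  arma::blas::gemm<double>(&tA, &tB, &m, &n, &k, &alpha,
                           A.begin(), &k, B.begin(), &k, &beta,
                           C.begin(), &m);
}

// Plain memcpy clone of a large matrix (a single pass; R-level arithmetic
// copies are much slower under memory pressure).
// [[Rcpp::export]]
NumericMatrix cpp_clone_matrix(const NumericMatrix &A) {
  NumericMatrix out(A.nrow(), A.ncol());
  std::memcpy(out.begin(), A.begin(), (size_t)A.nrow() * A.ncol() * sizeof(double));
  return out;
}

// Single-precision convolution forward used by the deep-feature backbone:
// the 224 x 224 stack is the pipeline's largest FLOP consumer and needs
// only feature-level (~1e-6 relative) precision; float GEMM roughly
// doubles throughput. The segmentation network keeps the double path.
static arma::fmat im2col_f32(const double *x, int H, int W, int C, int N,
                             int k, int s, int p, int Ho, int Wo) {
  const arma::uword rows = (arma::uword)N * Ho * Wo;
  arma::fmat col(rows, (arma::uword)k * k * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double *xc = xn + (size_t)H * W * c;
      for (int kw = 0; kw < k; ++kw) {
        const int owLo = std::max(0, ceil_div(p - kw, s));
        const int owHi = std::min(Wo - 1, floor_div(W - 1 + p - kw, s));
        for (int kh = 0; kh < k; ++kh) {
          const int ohLo = std::max(0, ceil_div(p - kh, s));
          const int ohHi = std::min(Ho - 1, floor_div(H - 1 + p - kh, s));
          if (ohHi < ohLo || owHi < owLo) continue;
          const arma::uword j = (arma::uword)kh + k * kw + (arma::uword)k * k * c;
          float *dst = col.colptr(j) + (arma::uword)Ho * Wo * n;
          for (int ow = owLo; ow <= owHi; ++ow) {
            const int iw = ow * s - p + kw;
            const double *src = xc + (size_t)H * iw;
            float *d2 = dst + (size_t)Ho * ow;
            for (int oh = ohLo; oh <= ohHi; ++oh)
              d2[oh] = (float)src[oh * s - p + kh];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd_f32(NumericVector x, const arma::mat &W,
                               const arma::vec &b, int k, int s, int p) {
  int d[4]; dims4(x, d);
  const int H = d[0], Wd = d[1], C = d[2], N = d[3];
  if ((int)W.n_rows != k * k * C) stop("weight rows != k*k*C");
  const int F = W.n_cols;
  const int Ho = out_dim(H, k, s, p), Wo = out_dim(Wd, k, s, p);
  if (Ho < 1 || Wo < 1) stop("convolution output dimension underflow");
  arma::fmat col = im2col_f32(REAL(x), H, Wd, C, N, k, s, p, Ho, Wo);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
  arma::fmat Y = col * Wf;
  Y.each_row() += bf;
  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  double *yp = REAL(y);
  const size_t plane = (size_t)Ho * Wo;
  for (int f = 0; f < F; ++f)
    for (int n = 0; n < N; ++n) {
      const float *src = Y.colptr(f) + plane * n;
      double *dst = yp + plane * (f + (size_t)F * n);
      for (size_t i = 0; i < plane; ++i) dst[i] = (double)src[i];
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return y;
}
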