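// Minimal convolutional kernels for the dorsal-stream trunk.
//
// Batches are R arrays with dim (H, W, C, N) (column-major), weights are
// arrays with dim (kh, kw, Cin, Cout).  Convolutions are implemented as
// im2col + GEMM; everything is single-threaded and bit-deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather padded input patches into a (kh*kw*Cin) x (Ho*Wo*N) matrix.
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const int K = kh * kw * C;
  arma::mat P(K, (arma::uword)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)H * W * C * n;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const arma::uword col = oh + (arma::uword)Ho * (ow + (arma::uword)Wo * n);
        double* pc = P.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)H * W * c;
          for (int kc = 0; kc < kw; ++kc) {
            const int w = ow * stride - pad + kc;
            if (w < 0 || w >= W) continue;
            for (int kr = 0; kr < kh; ++kr) {
              const int h = oh * stride - pad + kr;
              if (h < 0 || h >= H) continue;
              pc[kr + kh * (kc + kw * c)] = xc[h + (size_t)H * w];
            }
          }
        }
      }
    }
  }
  return P;
}

// Scatter-add a patch matrix back onto input-shaped gradients.
static void col2im(const arma::mat& P, double* gx, int H, int W, int C, int N,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* gn = gx + (size_t)H * W * C * n;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const arma::uword col = oh + (arma::uword)Ho * (ow + (arma::uword)Wo * n);
        const double* pc = P.colptr(col);
        for (int c = 0; c < C; ++c) {
          double* gc = gn + (size_t)H * W * c;
          for (int kc = 0; kc < kw; ++kc) {
            const int w = ow * stride - pad + kc;
            if (w < 0 || w >= W) continue;
            for (int kr = 0; kr < kh; ++kr) {
              const int h = oh * stride - pad + kr;
              if (h < 0 || h >= H) continue;
              gc[h + (size_t)H * w] += pc[kr + kh * (kc + kw * c)];
            }
          }
        }
      }
    }
  }
}

// Reshape weight array (kh, kw, Cin, Cout) into a (Cout x K) GEMM matrix.
static arma::mat weight_mat(const NumericVector& Wt, int kh, int kw, int C, int Cout) {
  const int K = kh * kw * C;
  arma::mat Wm(Cout, K);
  const double* wp = REAL(Wt);
  for (int co = 0; co < Cout; ++co)
    for (int k = 0; k < K; ++k)
      Wm(co, k) = wp[k + (size_t)K * co];
  return Wm;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector Wt, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("input channels do not match weight channels");
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("convolution output would be empty");

  arma::mat P = im2col(REAL(x), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm = weight_mat(Wt, kh, kw, C, Cout);
  arma::mat O = Wm * P;                       // Cout x (Ho*Wo*N)
  O.each_col() += arma::vec(REAL(b), Cout);

  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* op = REAL(out);
  for (arma::uword col = 0; col < O.n_cols; ++col) {
    const int n = col / ((arma::uword)Ho * Wo);
    const arma::uword hw = col - (arma::uword)n * Ho * Wo; // oh + Ho*ow
    for (int co = 0; co < Cout; ++co)
      op[hw % Ho + (size_t)Ho * (hw / Ho) + (size_t)Ho * Wo * (co + (size_t)Cout * n)] =
        O(co, col);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector Wt, NumericVector gout,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim"), gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  if (gd[2] != Cout || gd[3] != N) stop("gradient shape mismatch");

  // gout as Cout x (Ho*Wo*N)
  arma::mat G(Cout, (arma::uword)Ho * Wo * N);
  const double* gp = REAL(gout);
  for (arma::uword col = 0; col < G.n_cols; ++col) {
    const int n = col / ((arma::uword)Ho * Wo);
    const arma::uword hw = col - (arma::uword)n * Ho * Wo;
    for (int co = 0; co < Cout; ++co)
      G(co, col) = gp[hw % Ho + (size_t)Ho * (hw / Ho) + (size_t)Ho * Wo * (co + (size_t)Cout * n)];
  }

  arma::mat P = im2col(REAL(x), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm = weight_mat(Wt, kh, kw, C, Cout);

  arma::mat gWm = G * P.t();                  // Cout x K
  arma::vec gb = arma::sum(G, 1);
  arma::mat Pg = Wm.t() * G;                  // K x (Ho*Wo*N)

  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(REAL(gx), REAL(gx) + gx.size(), 0.0);
  col2im(Pg, REAL(gx), H, W, C, N, kh, kw, stride, pad, Ho, Wo);

  const int K = kh * kw * C;
  NumericVector gW((R_xlen_t)K * Cout);
  gW.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  double* gwp = REAL(gW);
  for (int co = 0; co < Cout; ++co)
    for (int k = 0; k < K; ++k)
      gwp[k + (size_t)K * co] = gWm(co, k);

  return List::create(_["gx"] = gx, _["gW"] = gW,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
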