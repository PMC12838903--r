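// Hot elementwise / pooling kernels of the CNN engine. Feature maps are
// passed as flat numeric vectors in channels-first layout; pooling views
// them as (M, W, B) with M = channels * space contiguous, W the pooled
// (time) axis and B the batch.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_lrelu(NumericVector x, double slope) {
  R_xlen_t n = x.size();
  NumericVector y(no_init(n));
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// gradient of leaky rectifier, recomputed from the forward input
// [[Rcpp::export]]
NumericVector cpp_lrelu_grad(NumericVector dy, NumericVector x,
                             double slope) {
  R_xlen_t n = x.size();
  NumericVector dx(no_init(n));
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* gp = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    gp[i] = xp[i] > 0 ? dp[i] : slope * dp[i];
  return dx;
}

// average pooling along W, width = stride = p, floor mode
// [[Rcpp::export]]
NumericVector cpp_avgpool_w(NumericVector x, int M, int W, int B, int p) {
  int To = W / p;
  NumericVector y(no_init((R_xlen_t)M * To * B));
  const double* xp = x.begin();
  double* yp = y.begin();
  double inv = 1.0 / p;
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (R_xlen_t)b * M * W;
    double* yb = yp + (R_xlen_t)b * M * To;
    for (int t = 0; t < To; ++t) {
      double* yt = yb + (R_xlen_t)t * M;
      const double* x0 = xb + (R_xlen_t)t * p * M;
      for (int m = 0; m < M; ++m) yt[m] = x0[m];
      for (int k = 1; k < p; ++k) {
        const double* xk = x0 + (R_xlen_t)k * M;
        for (int m = 0; m < M; ++m) yt[m] += xk[m];
      }
      for (int m = 0; m < M; ++m) yt[m] *= inv;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_w_grad(NumericVector dy, int M, int W, int B,
                                 int p) {
  int To = W / p;
  NumericVector dx((R_xlen_t)M * W * B); // zero-initialized (tail beyond To*p)
  const double* dp = dy.begin();
  double* gp = dx.begin();
  double inv = 1.0 / p;
  for (int b = 0; b < B; ++b) {
    const double* db = dp + (R_xlen_t)b * M * To;
    double* gb = gp + (R_xlen_t)b * M * W;
    for (int t = 0; t < To; ++t) {
      const double* dt = db + (R_xlen_t)t * M;
      for (int k = 0; k < p; ++k) {
        double* gk = gb + (R_xlen_t)(t * p + k) * M;
        for (int m = 0; m < M; ++m) gk[m] = dt[m] * inv;
      }
    }
  }
  return dx;
}

// max pooling along W; returns the pooled values and 1-based argmax offsets
// [[Rcpp::export]]
List cpp_maxpool_w(NumericVector x, int M, int W, int B, int p) {
  int To = W / p;
  NumericVector y(no_init((R_xlen_t)M * To * B));
  IntegerVector arg(no_init((R_xlen_t)M * To * B));
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (R_xlen_t)b * M * W;
    R_xlen_t off = (R_xlen_t)b * M * To;
    for (int t = 0; t < To; ++t) {
      double* yt = yp + off + (R_xlen_t)t * M;
      int* at = ap + off + (R_xlen_t)t * M;
      const double* x0 = xb + (R_xlen_t)t * p * M;
      for (int m = 0; m < M; ++m) { yt[m] = x0[m]; at[m] = 1; }
      for (int k = 1; k < p; ++k) {
        const double* xk = x0 + (R_xlen_t)k * M;
        for (int m = 0; m < M; ++m) {
          if (xk[m] > yt[m]) { yt[m] = xk[m]; at[m] = k + 1; }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_w_grad(NumericVector dy, IntegerVector arg,
                                 int M, int W, int B, int p) {
  int To = W / p;
  NumericVector dx((R_xlen_t)M * W * B);
  const double* dp = dy.begin();
  const int* ap = arg.begin();
  double* gp = dx.begin();
  for (int b = 0; b < B; ++b) {
    R_xlen_t off = (R_xlen_t)b * M * To;
    double* gb = gp + (R_xlen_t)b * M * W;
    for (int t = 0; t < To; ++t) {
      const double* dt = dp + off + (R_xlen_t)t * M;
      const int* at = ap + off + (R_xlen_t)t * M;
      double* g0 = gb + (R_xlen_t)t * p * M;
      for (int m = 0; m < M; ++m)
        g0[(R_xlen_t)(at[m] - 1) * M + m] = dt[m];
    }
  }
  return dx;
}
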