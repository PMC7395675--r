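// Fused elementwise kernels for the CNN training loop. The matrix products
// go through BLAS from R; these kernels remove the interpreter's temporary
// allocations on the large conv-layer intermediates. All *_inplace functions
// mutate their first argument, which the caller guarantees is unshared.

#include <Rcpp.h>
using namespace Rcpp;

// ReLU applied in place; returns its (mutated) argument.
// [[Rcpp::export]]
NumericVector relu_inplace(NumericVector z) {
  double* p = REAL(z);
  const R_xlen_t n = XLENGTH(z);
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  return z;
}

// ReLU gradient: zero the entries of d where the activation a was clipped.
// Shapes may differ (reshaped views of the same buffer); lengths must match.
// [[Rcpp::export]]
NumericVector relu_backward_inplace(NumericVector d, NumericVector a) {
  const R_xlen_t n = XLENGTH(d);
  if (XLENGTH(a) != n) stop("length mismatch in relu_backward_inplace");
  double* pd = REAL(d);
  const double* pa = REAL(a);
  for (R_xlen_t i = 0; i < n; ++i)
    if (pa[i] <= 0) pd[i] = 0;
  return d;
}

// im2col for a 1D convolution over a batch, with a leading column of ones so
// the bias folds into the kernel matrix. Input a is (n*l_in) x c_in with row
// index (sample, position) in column-major order; output is
// (n*l_out) x (1 + k*c_in), column (1 + (j-1)*c_in + c) holding channel c
// shifted by tap j. Pure contiguous copies.
// [[Rcpp::export]]
NumericMatrix im2col_ones(NumericMatrix a, int n, int l_in, int k) {
  const int c_in = a.ncol();
  const int l_out = l_in - k + 1;
  const R_xlen_t rows = (R_xlen_t)n * l_out;
  NumericMatrix m(rows, 1 + k * c_in);
  double* pm = REAL(m);
  const double* pa = REAL(a);
  for (R_xlen_t r = 0; r < rows; ++r) pm[r] = 1.0;
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < c_in; ++c) {
      const double* src = pa + (R_xlen_t)c * n * l_in + (R_xlen_t)j * n;
      double* dst = pm + ((R_xlen_t)(1 + j * c_in + c)) * rows;
      std::copy(src, src + rows, dst);
    }
  }
  return m;
}

// Scatter the gradient at the im2col patches (without the ones column) back
// onto the conv layer's input: the adjoint of im2col_ones' copy pattern.
// [[Rcpp::export]]
NumericMatrix conv_input_grad(NumericMatrix dm, int n, int l_in, int k,
                              int c_in) {
  const int l_out = l_in - k + 1;
  const R_xlen_t rows = (R_xlen_t)n * l_out;
  if ((R_xlen_t)dm.nrow() != rows || dm.ncol() != k * c_in)
    stop("dm has wrong shape in conv_input_grad");
  NumericMatrix da((R_xlen_t)n * l_in, c_in);
  double* pd = REAL(da);
  const double* pm = REAL(dm);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < c_in; ++c) {
      double* dst = pd + (R_xlen_t)c * n * l_in + (R_xlen_t)j * n;
      const double* src = pm + ((R_xlen_t)(j * c_in + c)) * rows;
      for (R_xlen_t r = 0; r < rows; ++r) dst[r] += src[r];
    }
  }
  return da;
}

// One Adam step, fused and in place: updates the first and second moment
// estimates and the parameters in a single pass. lr_t is the bias-corrected
// step size lr * sqrt(1 - b2^t) / (1 - b1^t).
// [[Rcpp::export]]
void adam_step_inplace(NumericVector w, NumericVector m, NumericVector v,
                       NumericVector g, double lr_t, double b1, double b2,
                       double eps) {
  const R_xlen_t n = XLENGTH(w);
  if (XLENGTH(m) != n || XLENGTH(v) != n || XLENGTH(g) != n)
    stop("length mismatch in adam_step_inplace");
  double* pw = REAL(w);
  double* pm = REAL(m);
  double* pv = REAL(v);
  const double* pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pw[i] -= lr_t * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}
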