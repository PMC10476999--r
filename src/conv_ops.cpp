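// Minimal 2-D multi-channel convolution primitives (same zero padding,
// odd square kernels) used by the reference residual denoiser. Forward and
// backward passes are expressed as shifted submatrix axpy operations so
// Armadillo vectorizes the inner loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// weights come in as a 4-D array (k, k, c_in, c_out) flattened column-major
static inline double wget(const Rcpp::NumericVector& w, int k, int ci_n,
                          int ky, int kx, int ci, int co) {
  return w[ky + k * (kx + k * (ci + ci_n * co))];
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& input, const Rcpp::NumericVector& weights,
                      const arma::vec& bias) {
  Rcpp::IntegerVector wd = weights.attr("dim");
  const int k = wd[0], ci_n = wd[2], co_n = wd[3];
  const int h = input.n_rows, w = input.n_cols, pad = k / 2;
  cube out(h, w, co_n);
  for (int co = 0; co < co_n; ++co) out.slice(co).fill(bias[co]);
  for (int co = 0; co < co_n; ++co)
    for (int ci = 0; ci < ci_n; ++ci)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const double wv = wget(weights, k, ci_n, ky, kx, ci, co);
          if (wv == 0.0) continue;
          const int dy = ky - pad, dx = kx - pad;
          const int r0 = std::max(0, -dy), r1 = std::min(h - 1, h - 1 - dy);
          const int c0 = std::max(0, -dx), c1 = std::min(w - 1, w - 1 - dx);
          if (r0 > r1 || c0 > c1) continue;
          out.slice(co).submat(r0, c0, r1, c1) +=
            wv * input.slice(ci).submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx);
        }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& input, const Rcpp::NumericVector& weights,
                      const arma::cube& grad_out) {
  Rcpp::IntegerVector wd = weights.attr("dim");
  const int k = wd[0], ci_n = wd[2], co_n = wd[3];
  const int h = input.n_rows, w = input.n_cols, pad = k / 2;
  cube gin(h, w, ci_n, fill::zeros);
  Rcpp::NumericVector gw(weights.size());
  gw.attr("dim") = wd;
  vec gb(co_n, fill::zeros);
  for (int co = 0; co < co_n; ++co) gb[co] = accu(grad_out.slice(co));
  for (int co = 0; co < co_n; ++co)
    for (int ci = 0; ci < ci_n; ++ci)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int dy = ky - pad, dx = kx - pad;
          const int r0 = std::max(0, -dy), r1 = std::min(h - 1, h - 1 - dy);
          const int c0 = std::max(0, -dx), c1 = std::min(w - 1, w - 1 - dx);
          if (r0 > r1 || c0 > c1) continue;
          const double wv = wget(weights, k, ci_n, ky, kx, ci, co);
          // dL/dW = <input shifted, grad_out>
          gw[ky + k * (kx + k * (ci + ci_n * co))] =
            accu(input.slice(ci).submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx) %
                 grad_out.slice(co).submat(r0, c0, r1, c1));
          if (wv != 0.0)
            gin.slice(ci).submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx) +=
              wv * grad_out.slice(co).submat(r0, c0, r1, c1);
        }
  return Rcpp::List::create(Rcpp::Named("grad_input") = gin,
                            Rcpp::Named("grad_weights") = gw,
                            Rcpp::Named("grad_bias") = gb);
}
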