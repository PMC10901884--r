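// Batched 1-D convolution kernels (im2col gather + BLAS GEMM + col2im
// scatter) for the neural classifier. The index map comes from R
// (conv_plan): idx is k x L_out with 1-based positions into the padded
// signal; positions landing in the padding read/accumulate zeros. The
// im2col matrix never crosses the R/C++ boundary: the backward pass
// regathers it from the cached layer input, which is cheaper than
// round-tripping a multi-megabyte matrix per call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat gather_cols(const double* xp, int C, int L, int B,
                             const IntegerMatrix& idx, int pad) {
  const int k = idx.nrow(), Lo = idx.ncol();
  arma::mat Xcol(C * k, (size_t)Lo * B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const double* xb = xp + (size_t)C * L * bb;
    for (int t = 0; t < Lo; ++t) {
      double* col = Xcol.colptr((size_t)Lo * bb + t);
      for (int kk = 0; kk < k; ++kk) {
        const int l = idx(kk, t) - 1 - pad;
        if (l >= 0 && l < L) {
          std::copy(xb + (size_t)C * l, xb + (size_t)C * (l + 1),
                    col + (size_t)C * kk);
        }
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(const NumericVector& X, const arma::mat& W,
                          const arma::vec& b, const IntegerMatrix& idx,
                          int pad, bool relu) {
  IntegerVector xdim = X.attr("dim");
  const int C = xdim[0], L = xdim[1], B = xdim[2];
  const int Lo = idx.ncol();
  arma::mat Xcol = gather_cols(X.begin(), C, L, B, idx, pad);
  arma::mat Y = W * Xcol;
  Y.each_col() += b;
  if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  NumericVector Yv(Y.begin(), Y.end());
  Yv.attr("dim") = IntegerVector::create((int)W.n_rows, Lo, B);
  return Yv;
}

// dY: (Co, Lo, B). X: the layer input that was fed to cpp_conv_fw.
// If `relu_out` is non-NULL (the layer's rectified output), dY is first
// masked by (out > 0), i.e. the ReLU backward is fused here.
// [[Rcpp::export]]
List cpp_conv_bw(const NumericVector& dY, const arma::mat& W,
                 const NumericVector& X, const IntegerMatrix& idx, int pad,
                 bool need_dx, Nullable<NumericVector> relu_out) {
  IntegerVector ydim = dY.attr("dim");
  IntegerVector xdim = X.attr("dim");
  const int Co = ydim[0], Lo = ydim[1], B = ydim[2];
  const int C = xdim[0], L = xdim[1];
  arma::mat dYm(const_cast<double*>(dY.begin()), Co, (size_t)Lo * B,
                false, true);
  arma::mat dYmask;
  if (relu_out.isNotNull()) {
    NumericVector ro(relu_out);
    dYmask = dYm;               // copy, then mask in place
    double* p = dYmask.memptr();
    const double* o = ro.begin();
    const size_t n = dYmask.n_elem;
    for (size_t i = 0; i < n; ++i) {
      if (o[i] <= 0.0) p[i] = 0.0;
    }
  }
  const arma::mat& dYu = relu_out.isNotNull() ? dYmask : dYm;
  arma::mat Xcol = gather_cols(X.begin(), C, L, B, idx, pad);
  arma::mat dW = dYu * Xcol.t();
  arma::vec db = arma::sum(dYu, 1);
  List out = List::create(_["dW"] = dW,
                          _["db"] = NumericVector(db.begin(), db.end()),
                          _["dX"] = R_NilValue);
  if (!need_dx) return out;
  arma::mat dXcol = W.t() * dYu;
  NumericVector dX((size_t)C * L * B);
  double* dxp = dX.begin();
  const int k = idx.nrow();
  for (int bb = 0; bb < B; ++bb) {
    double* dxb = dxp + (size_t)C * L * bb;
    for (int t = 0; t < Lo; ++t) {
      const double* col = dXcol.colptr((size_t)Lo * bb + t);
      for (int kk = 0; kk < k; ++kk) {
        const int l = idx(kk, t) - 1 - pad;
        if (l >= 0 && l < L) {
          double* dst = dxb + (size_t)C * l;
          const double* src = col + (size_t)C * kk;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(C, L, B);
  out["dX"] = dX;
  return out;
}
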