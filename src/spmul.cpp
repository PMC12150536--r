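// Iterated sparse-dense products y = A^k x for a CSC symmetric
// matrix, used by the multi-scale convolution layers (A^k is never
// materialized).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".spmulIterCpp")]]
arma::mat spmulIterCpp(Rcpp::IntegerVector p, Rcpp::IntegerVector i,
                       Rcpp::NumericVector x, const arma::mat& X,
                       int times) {
  const arma::uword n = p.size() - 1;
  const arma::uword d = X.n_cols;
  const int* pp = p.begin();
  const int* ii = i.begin();
  const double* xx = x.begin();
  arma::mat cur = X;
  arma::mat nxt(n, d);
  for (int t = 0; t < times; ++t) {
    nxt.zeros();
    for (arma::uword j = 0; j < d; ++j) {
      const double* c = cur.colptr(j);
      double* o = nxt.colptr(j);
      for (arma::uword col = 0; col < n; ++col) {
        const double cv = c[col];
        for (int idx = pp[col]; idx < pp[col + 1]; ++idx)
          o[ii[idx]] += xx[idx] * cv;
      }
    }
    cur.swap(nxt);
  }
  return cur;
}
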