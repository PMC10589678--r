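#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ln(communicability) along a node-removal sequence. Removal zeroes a node's
// row and column; the full-size communicability equals the matrix-exponential
// sum over the remaining submatrix plus one per removed (all-zero) node.
// order: 1-based removal sequence; returns length n_steps + 1 (step 0 first).
// [[Rcpp::export]]
NumericVector cpp_attack_lnC(NumericMatrix adj, IntegerVector order,
                             int n_steps) {
  int n = adj.nrow();
  arma::mat A(adj.begin(), n, n, true);
  NumericVector out(n_steps + 1);
  std::vector<char> removed(n, 0);
  for (int step = 0; step <= n_steps; ++step) {
    if (step > 0) removed[order[step - 1] - 1] = 1;
    arma::uvec keep(n - step);
    int t = 0;
    for (int v = 0; v < n; ++v) if (!removed[v]) keep[t++] = v;
    arma::mat sub = A.submat(keep, keep);
    arma::mat E = arma::expmat_sym(sub);
    out[step] = std::log(arma::accu(E) + step);
  }
  return out;
}
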