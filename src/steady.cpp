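#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batch steady-state solve: one stationarity system per condition.
// rates: n_cond x n_edges matrix of evaluated edge rate constants;
// from/to: 1-based state indices per edge.
// [[Rcpp::export]]
arma::mat steady_batch_cpp(const arma::mat& rates,
                           const IntegerVector& from,
                           const IntegerVector& to,
                           int n_states) {
  const int n_cond = rates.n_rows;
  const int n_edge = rates.n_cols;
  if (from.size() != n_edge || to.size() != n_edge)
    stop("edge index length mismatch");
  arma::mat P(n_cond, n_states);
  arma::mat A(n_states, n_states);
  arma::vec b(n_states, arma::fill::zeros);
  b(n_states - 1) = 1.0;
  arma::vec x;
  for (int c = 0; c < n_cond; ++c) {
    A.zeros();
    for (int e = 0; e < n_edge; ++e) {
      const double r = rates(c, e);
      const int i = from[e] - 1, j = to[e] - 1;
      A(j, i) += r;   // transpose of the generator
      A(i, i) -= r;
    }
    A.row(n_states - 1).ones();
    const bool ok = arma::solve(x, A, b, arma::solve_opts::no_approx);
    if (!ok)
      stop("singular stationarity system at condition %d", c + 1);
    P.row(c) = x.t();
  }
  return P;
}
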