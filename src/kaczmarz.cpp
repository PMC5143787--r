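#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// One full sequential Kaczmarz sweep, operating on the transposed system
// matrix (N x M, one column per row of B) so each row access is contiguous.
// Rows with norm <= 1e-14 * max row norm are skipped.
// [[Rcpp::export]]
arma::vec kaczmarz_sweep_t(const arma::mat& Bt, const arma::vec& y, arma::vec x) {
  const arma::uword M = Bt.n_cols;
  if (y.n_elem != M || x.n_elem != Bt.n_rows)
    Rcpp::stop("shape error: incompatible dimensions in Kaczmarz sweep");

  arma::vec rn2(M);
  for (arma::uword i = 0; i < M; ++i) rn2(i) = arma::dot(Bt.col(i), Bt.col(i));
  const double max_norm = std::sqrt(rn2.max());
  if (max_norm == 0.0) Rcpp::stop("degenerate input: all rows are zero");
  const double skip2 = std::pow(1e-14 * max_norm, 2);

  for (arma::uword i = 0; i < M; ++i) {
    if (rn2(i) <= skip2) continue;
    const double r = y(i) - arma::dot(Bt.col(i), x);
    x += (r / rn2(i)) * Bt.col(i);
  }
  return x;
}
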