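// Metric MDS by stress majorization (SMACOF, unit weights).
// Iterates the Guttman transform from a given initial configuration and
// returns the configuration together with its normalized stress (stress-1).
// The Gram matrix is formed in BLAS; the elementwise work (distances, the
// B-matrix coefficients, the stress sum) is fused into one pass over the
// upper triangle to avoid large temporaries.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List smacof_engine(const arma::mat& D, const arma::mat& X0,
                         int max_iter, double tol) {
  const uword n = D.n_rows;
  double denom = 0.0;
  for (uword j = 0; j < n; ++j)
    for (uword i = 0; i < j; ++i) denom += D(i, j) * D(i, j);

  mat X = X0;
  mat R(n, n);
  vec r(n);
  double s_prev = -1.0;
  int iter = 0;

  for (iter = 0; iter <= max_iter; ++iter) {
    // distances + stress + majorization coefficients in one triangular pass
    mat G = X * X.t();
    vec g = G.diag();
    double num = 0.0;
    r.zeros();
    for (uword j = 0; j < n; ++j) {
      R(j, j) = 0.0;
      for (uword i = 0; i < j; ++i) {
        double d2 = g(i) + g(j) - 2.0 * G(i, j);
        double dh = (d2 > 0.0) ? std::sqrt(d2) : 0.0;
        double e = D(i, j) - dh;
        num += e * e;
        double rij = (dh > 1e-12) ? D(i, j) / dh : 0.0;
        R(i, j) = rij;
        R(j, i) = rij;
        r(i) += rij;
        r(j) += rij;
      }
    }
    double s = (denom > 0.0) ? std::sqrt(num / denom) : 0.0;
    bool converged = (s_prev >= 0.0) && (std::abs(s_prev - s) < tol);
    s_prev = s;
    if (converged || iter == max_iter) break;

    // Guttman transform: X <- (1/n) [diag(r) - R] X
    X = (X.each_col() % r - R * X) / static_cast<double>(n);
  }
  return Rcpp::List::create(Rcpp::Named("X") = X,
                            Rcpp::Named("stress") = s_prev,
                            Rcpp::Named("iterations") = iter);
}
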