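#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   minimize ||A x - b||_2  subject to  x >= 0.
// Deterministic: ties in the gradient are broken by lowest column index
// (arma::index_max returns the first maximum).
// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b,
                    double tol = -1.0, int maxiter = -1) {
  const uword n = A.n_cols;
  if (maxiter < 0) maxiter = 3 * static_cast<int>(n);
  if (tol < 0) tol = 10.0 * datum::eps * norm(A, 1) * static_cast<double>(A.n_rows);

  vec x(n, fill::zeros);
  std::vector<uword> passive;           // indices with x > 0
  std::vector<bool> in_passive(n, false);
  vec w = A.t() * (b - A * x);          // dual / negative gradient

  int outer = 0;
  while (passive.size() < n && outer < maxiter) {
    // most positive dual among active (zero) coordinates
    double wmax = tol;
    sword jmax = -1;
    for (uword j = 0; j < n; ++j) {
      if (!in_passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax < 0) break;                // KKT satisfied
    ++outer;

    in_passive[jmax] = true;
    passive.push_back(static_cast<uword>(jmax));

    // inner loop: solve unconstrained LS on the passive set, move back
    // any coordinate that went non-positive
    for (;;) {
      uvec P = conv_to<uvec>::from(passive);
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::fast + solve_opts::no_approx);
      if (!ok) solve(z, A.cols(P), b);  // fall back to pivoted solve

      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step toward z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < P.n_elem; ++k) {
        if (z(k) <= 0) {
          double xk = x(P(k));
          double a = xk / (xk - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < P.n_elem; ++k)
        x(P(k)) += alpha * (z(k) - x(P(k)));
      // drop coordinates at (numerical) zero from the passive set
      std::vector<uword> keep;
      for (uword k = 0; k < P.n_elem; ++k) {
        if (x(P(k)) > tol) keep.push_back(P(k));
        else { x(P(k)) = 0.0; in_passive[P(k)] = false; }
      }
      passive = keep;
      if (passive.empty()) break;
    }
    w = A.t() * (b - A * x);
  }

  vec resid = b - A * x;
  return Rcpp::List::create(
    Rcpp::Named("x") = Rcpp::NumericVector(x.begin(), x.end()),
    Rcpp::Named("rnorm") = norm(resid, 2),
    Rcpp::Named("iterations") = outer);
}
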