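// Coordinate descent for the weighted LASSO
//   argmin_b ||y - X b||_2^2 + sum_k pen_k |b_k|
// on the Gram parameterisation (G = X'X, xty = X'y), with warm starts
// along a descending lambda path. Per-coefficient penalties carry the
// prior reinforcement (pen_k = bias * lambda for prior-supported edges).
// An infinite penalty excludes a predictor (used for self-edges).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double cd_update(const arma::mat& G, const arma::vec& xty,
                               const arma::vec& pen, arma::vec& b,
                               arma::vec& Gb, arma::uword k) {
  const double gkk = G(k, k);
  if (gkk <= 0.0 || !std::isfinite(pen[k])) {
    if (b[k] != 0.0) { Gb -= b[k] * G.col(k); double d = std::fabs(b[k]);
      b[k] = 0.0; return d; }
    return 0.0;
  }
  // z = 2 * x_k'(y - X b_{-k}); soft-threshold at pen_k
  const double z = 2.0 * (xty[k] - Gb[k] + gkk * b[k]);
  double bnew = 0.0;
  if (z > pen[k])       bnew = (z - pen[k]) / (2.0 * gkk);
  else if (z < -pen[k]) bnew = (z + pen[k]) / (2.0 * gkk);
  const double del = bnew - b[k];
  if (del != 0.0) { Gb += del * G.col(k); b[k] = bnew; }
  return std::fabs(del);
}

// Full sweeps establish the active set; inner sweeps iterate it to
// convergence; terminate when a full sweep itself moves nothing.
static void cd_solve(const arma::mat& G, const arma::vec& xty,
                     const arma::vec& pen, arma::vec& b,
                     double tol, int maxit) {
  const arma::uword p = G.n_rows;
  arma::vec Gb = G * b;
  int used = 0;
  while (used < maxit) {
    double maxdel = 0.0;
    for (arma::uword k = 0; k < p; ++k)
      maxdel = std::max(maxdel, cd_update(G, xty, pen, b, Gb, k));
    ++used;
    if (maxdel < tol) break;
    arma::uvec act = arma::find(b != 0.0);
    while (used < maxit) {
      double d = 0.0;
      for (arma::uword a = 0; a < act.n_elem; ++a)
        d = std::max(d, cd_update(G, xty, pen, b, Gb, act[a]));
      ++used;
      if (d < tol) break;
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".lasso_path_single")]]
arma::mat lasso_path_single(const arma::mat& G, const arma::vec& xty,
                            const arma::vec& pf, const arma::vec& lambdas,
                            double tol = 1e-11, int maxit = 100000) {
  const arma::uword p = G.n_rows, nl = lambdas.n_elem;
  arma::mat out(p, nl, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  for (arma::uword l = 0; l < nl; ++l) {
    arma::vec pen = pf * lambdas[l];
    cd_solve(G, xty, pen, b, tol, maxit);
    out.col(l) = b;
  }
  return out;
}

// One warm-started step of every gene model at a single lambda: B0 holds
// the coefficients from the previous (larger) lambda and is updated in
// place semantics (returned).
//' @noRd
// [[Rcpp::export(name = ".lasso_multi_fit_warm")]]
arma::mat lasso_multi_fit_warm(const arma::mat& G, const arma::mat& XtY,
                               const arma::mat& PF, double lambda,
                               arma::mat B0,
                               double tol = 1e-7, int maxit = 100000) {
  const arma::uword g = XtY.n_cols;
  for (arma::uword j = 0; j < g; ++j) {
    arma::vec b = B0.col(j);
    arma::vec pen = PF.col(j) * lambda;
    cd_solve(G, XtY.col(j), pen, b, tol, maxit);
    B0.col(j) = b;
  }
  return B0;
}

// Full-data refit of every gene model at a single lambda.
//' @noRd
// [[Rcpp::export(name = ".lasso_multi_fit")]]
arma::mat lasso_multi_fit(const arma::mat& G, const arma::mat& XtY,
                          const arma::mat& PF, double lambda,
                          double tol = 1e-11, int maxit = 100000) {
  const arma::uword p = G.n_rows, g = XtY.n_cols;
  arma::mat B(p, g, arma::fill::zeros);
  for (arma::uword j = 0; j < g; ++j) {
    arma::vec b(p, arma::fill::zeros);
    arma::vec pen = PF.col(j) * lambda;
    cd_solve(G, XtY.col(j), pen, b, tol, maxit);
    B.col(j) = b;
  }
  return B;
}
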