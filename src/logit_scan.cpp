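#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-SNP additive-dosage logistic regression with a shared covariate block.
// Newton-Raphson warm-started from the covariate-only fit; gradient tolerance
// and iteration cap fixed by the caller for determinism. Returns beta and
// Wald SE of the dosage term plus a convergence flag.
// [[Rcpp::export]]
Rcpp::List logit_scan_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::mat& G, const arma::vec& start,
                          double tol, int maxit) {
  const uword n = X.n_rows, c = X.n_cols, m = G.n_cols;
  vec beta(m, fill::zeros), se(m, fill::zeros);
  ivec conv(m, fill::zeros), iters(m, fill::zeros);

  for (uword j = 0; j < m; ++j) {
    vec b(c + 1, fill::zeros);
    b.head(c) = start;
    const vec g = G.col(j);
    bool ok = false, failed = false;
    mat H(c + 1, c + 1);
    int it = 0;
    for (it = 0; it < maxit; ++it) {
      vec eta = X * b.head(c) + g * b(c);
      eta = clamp(eta, -30.0, 30.0);
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      vec r = y - mu;
      vec grad(c + 1);
      grad.head(c) = X.t() * r;
      grad(c) = dot(g, r);
      mat Xw = X.each_col() % w;
      H.submat(0, 0, c - 1, c - 1) = X.t() * Xw;
      vec xg = Xw.t() * g;
      H.submat(0, c, c - 1, c) = xg;
      H.submat(c, 0, c, c - 1) = xg.t();
      H(c, c) = dot(g, w % g);
      if (grad.has_nan() || !H.is_finite()) { failed = true; break; }
      if (norm(grad, "inf") < tol) { ok = true; break; }
      vec step;
      if (!solve(step, H, grad, solve_opts::no_approx)) { failed = true; break; }
      b += step;
      if (!b.is_finite() || std::abs(b(c)) > 50.0) { failed = true; break; }
    }
    iters(j) = it;
    if (ok && !failed) {
      mat Hinv;
      if (inv_sympd(Hinv, H) && Hinv(c, c) > 0) {
        beta(j) = b(c);
        se(j) = std::sqrt(Hinv(c, c));
        conv(j) = (std::abs(b(c)) < 20.0 && std::isfinite(se(j))) ? 1 : 0;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("se") = se,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("iterations") = iters);
}
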