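// Batched Lawson-Hanson non-negative least squares.
// Problem sizes here are tiny (K ~ 5-53 wavelengths, N ~ 2-5 chromophores)
// but the solver is called once per fingerprint / image pixel, so the whole
// batch loop lives in C++.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Solve min ||A x - b|| s.t. x >= 0 for one right-hand side.
// Active-set entry ties are broken by lowest column index (strict '>').
static void nnls_one(const mat& A, const vec& b, vec& x, double& rnorm) {
  const uword n = A.n_cols;
  x.zeros(n);
  std::vector<bool> passive(n, false);
  vec w = A.t() * b;
  const double tol = 10.0 * datum::eps * norm(A, 1) *
                     static_cast<double>(std::max(A.n_rows, A.n_cols));
  const int maxit = 3 * static_cast<int>(n) + 30;
  int it = 0;
  uvec pidx;

  while (it++ < maxit) {
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = static_cast<int>(j); }
    }
    if (t < 0) break;  // KKT satisfied
    passive[t] = true;

    // inner loop: least squares on the passive set, backtrack if infeasible
    for (;;) {
      std::vector<uword> pv;
      for (uword j = 0; j < n; ++j) if (passive[j]) pv.push_back(j);
      pidx = uvec(pv);
      mat Ap = A.cols(pidx);
      vec z;
      bool ok = solve(z, Ap, b);
      if (!ok) z = pinv(Ap) * b;

      if (z.min() > 0) {
        x.zeros(n);
        x(pidx) = z;
        break;
      }
      // step toward z as far as feasibility allows, drop zeroed variables
      double alpha = datum::inf;
      for (uword k = 0; k < pidx.n_elem; ++k) {
        if (z(k) <= 0) {
          double xj = x(pidx(k));
          double a = xj / (xj - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < pidx.n_elem; ++k) {
        uword j = pidx(k);
        x(j) += alpha * (z(k) - x(j));
        if (x(j) <= 1e-14) { x(j) = 0.0; passive[j] = false; }
      }
    }
    w = A.t() * (b - A * x);
  }
  rnorm = norm(A * x - b, 2);
}

// [[Rcpp::export]]
Rcpp::List nnls_batch_cpp(const arma::mat& M, const arma::mat& F) {
  // M: K x N library, F: n x K fingerprints (rows)
  const uword n = F.n_rows, N = M.n_cols;
  if (F.n_cols != M.n_rows) Rcpp::stop("fingerprint length does not match library rows");
  mat coef(n, N, fill::zeros);
  vec rnorm(n, fill::zeros);
  vec x(N);
  double r;
  for (uword i = 0; i < n; ++i) {
    vec b = F.row(i).t();
    if (!b.is_finite()) Rcpp::stop("non-finite amplitudes in fingerprint %d", (int)(i + 1));
    nnls_one(M, b, x, r);
    coef.row(i) = x.t();
    rnorm(i) = r;
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = coef,
                            Rcpp::Named("residual_norm") = rnorm);
}
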