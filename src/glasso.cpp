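// Graphical lasso by block coordinate descent.
//
// For a covariance/correlation matrix S and penalty lambda, maximizes
//   log det(Omega) - trace(S Omega) - lambda * sum_{i != j} |Omega_ij|
// over positive-definite Omega (diagonal optionally penalized as well).
// Each column update solves a lasso problem on the partitioned working
// covariance W by cyclic coordinate descent; the precision matrix is
// recovered from the final regression coefficients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void lasso_cd(const mat& W11, const vec& s12, double lambda, vec& beta,
                     double tol, int maxit) {
  const uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < q; ++j) {
      double r = s12(j) - dot(W11.col(j), beta) + W11(j, j) * beta(j);
      double bj = 0.0;
      if (r > lambda) bj = (r - lambda) / W11(j, j);
      else if (r < -lambda) bj = (r + lambda) / W11(j, j);
      double d = std::fabs(bj - beta(j));
      if (d > dmax) dmax = d;
      beta(j) = bj;
    }
    if (dmax < tol) break;
  }
}

// Single glasso fit with warm starts supplied via W and B (modified in place).
static bool glasso_one(const mat& S, double lambda, bool penalize_diagonal,
                       mat& W, mat& B, mat& Omega, double tol, int maxit) {
  const uword p = S.n_rows;
  // working covariance keeps the diagonal fixed at S_ii (+ lambda if penalized)
  for (uword j = 0; j < p; ++j)
    W(j, j) = S(j, j) + (penalize_diagonal ? lambda : 0.0);

  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    mat W_old = W;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(regspace<uvec>(0, p - 1) != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      beta = beta.elem(idx);
      lasso_cd(W11, s12, lambda, beta, tol * 0.1, 10000);
      vec w12 = W11 * beta;
      for (uword k = 0; k < idx.n_elem; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (abs(W - W_old).max() < tol) { converged = true; break; }
  }

  // recover the precision matrix from the regression coefficients
  Omega.zeros(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(regspace<uvec>(0, p - 1) != j);
    vec beta = B.col(j);
    beta = beta.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
    Omega(j, j) = theta_jj;
    for (uword k = 0; k < idx.n_elem; ++k)
      Omega(idx(k), j) = -beta(k) * theta_jj;
  }
  Omega = 0.5 * (Omega + Omega.t());
  return converged;
}

// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           bool penalize_diagonal, double tol, int maxit,
                           double zero_tol) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  cube omegas(p, p, L);
  Rcpp::LogicalVector conv(L);
  vec logdet(L), trace_so(L);
  ivec edges(L);

  mat W = S;   // warm start carried down the (descending) path
  mat B(p, p, fill::zeros);
  mat Omega(p, p);
  for (uword l = 0; l < L; ++l) {
    conv[l] = glasso_one(S, lambdas(l), penalize_diagonal, W, B, Omega,
                         tol, maxit);
    omegas.slice(l) = Omega;
    double val, sign;
    log_det(val, sign, Omega);
    logdet(l) = (sign > 0) ? val : datum::nan;
    trace_so(l) = accu(S % Omega);
    int e = 0;
    for (uword i = 0; i < p; ++i)
      for (uword j = i + 1; j < p; ++j)
        if (std::fabs(Omega(i, j)) > zero_tol) ++e;
    edges(l) = e;
  }
  return Rcpp::List::create(Rcpp::Named("omega") = omegas,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("logdet") = logdet,
                            Rcpp::Named("trace_so") = trace_so,
                            Rcpp::Named("edges") = edges);
}

// [[Rcpp::export]]
Rcpp::List glasso_fit_cpp(const arma::mat& S, double lambda,
                          bool penalize_diagonal, double tol, int maxit) {
  const uword p = S.n_rows;
  mat W = S;
  mat B(p, p, fill::zeros);
  mat Omega(p, p);
  bool converged = glasso_one(S, lambda, penalize_diagonal, W, B, Omega,
                              tol, maxit);
  return Rcpp::List::create(Rcpp::Named("omega") = Omega,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("converged") = converged);
}
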