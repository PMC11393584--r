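// Sparse inverse-covariance estimation by block coordinate descent
// (graphical lasso). The L1 penalty is applied to off-diagonal precision
// entries only; the diagonal is unpenalized, so the working covariance W
// keeps diag(W) = diag(S) throughout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso sub-problem for one column: min 0.5 b'Vb - u'b + lambda ||b||_1.
// Coordinate descent on b, warm-started from the previous sweep.
static void lasso_cd(const mat& V, const vec& u, double lambda, vec& b,
                     double tol, int maxit) {
  const uword m = b.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < m; ++k) {
      double old = b[k];
      // residual gradient excluding k
      double r = u[k] - dot(V.col(k), b) + V(k, k) * old;
      double bnew = soft(r, lambda) / V(k, k);
      if (bnew != old) {
        b[k] = bnew;
        double d = std::abs(bnew - old);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < tol) break;
  }
}

// One glasso fit. W and B (p x p matrix whose column j holds beta_j with a
// structural zero at row j) are updated in place so paths can warm-start.
static void glasso_one(const mat& S, double lambda, mat& W, mat& B,
                       double tol, int maxit, bool& converged) {
  const uword p = S.n_rows;
  converged = false;
  if (p == 1) { W = S; converged = true; return; }
  mat V(p - 1, p - 1);
  vec u(p - 1), b(p - 1), w12(p - 1);
  uvec idx(p - 1);
  for (int sweep = 0; sweep < maxit; ++sweep) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uword c = 0;
      for (uword k = 0; k < p; ++k) if (k != j) idx[c++] = k;
      V = W.submat(idx, idx);
      u = S.col(j);
      u = u.elem(idx);
      b = B.col(j);
      b = b.elem(idx);
      lasso_cd(V, u, lambda, b, tol, maxit);
      w12 = V * b;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx[k], j) - w12[k]);
        if (d > dmax) dmax = d;
        W(idx[k], j) = w12[k];
        W(j, idx[k]) = w12[k];
        B(idx[k], j) = b[k];
      }
    }
    if (dmax < tol) { converged = true; break; }
  }
}

// Recover the precision matrix from the converged W and B.
static mat theta_from_wb(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double q = W(j, j);
    for (uword k = 0; k < p; ++k) if (k != j) q -= W(k, j) * B(k, j);
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k) if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());
  // entries that are zero in both directed solves stay exactly zero after
  // averaging; clip symmetrization dust so the sparsity pattern is exact
  for (uword j = 0; j < p; ++j)
    for (uword k = 0; k < p; ++k)
      if (k != j && std::abs(Theta(k, j)) < 1e-10) Theta(k, j) = 0.0;
  return Theta;
}

// [[Rcpp::export(name = ".glasso_fit_cpp")]]
Rcpp::List glasso_fit_cpp(const arma::mat& S, double lambda,
                          double tol = 1e-6, int maxit = 10000) {
  mat W = S;
  mat B(S.n_rows, S.n_rows, fill::zeros);
  bool conv = false;
  glasso_one(S, lambda, W, B, tol, maxit, conv);
  mat Theta = theta_from_wb(W, B);
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("converged") = conv);
}

// Path fit with warm starts, descending lambda. Returns a (p*p) x nlambda
// matrix of vectorized precision matrices plus per-lambda EBIC ingredients.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-6, int maxit = 10000) {
  const uword p = S.n_rows, nl = lambdas.n_elem;
  mat W = S;
  mat B(p, p, fill::zeros);
  mat thetas(p * p, nl);
  vec loglik_core(nl);   // log det Theta - tr(S Theta)
  ivec nedges(nl);
  ivec convs(nl);
  for (uword i = 0; i < nl; ++i) {
    bool conv = false;
    glasso_one(S, lambdas[i], W, B, tol, maxit, conv);
    mat Theta = theta_from_wb(W, B);
    thetas.col(i) = vectorise(Theta);
    double ld, sign;
    log_det(ld, sign, Theta);
    loglik_core[i] = ld - trace(S * Theta);
    int e = 0;
    for (uword a = 0; a < p; ++a)
      for (uword bcol = a + 1; bcol < p; ++bcol)
        if (Theta(a, bcol) != 0.0) ++e;
    nedges[i] = e;
    convs[i] = conv ? 1 : 0;
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("loglik_core") = loglik_core,
                            Rcpp::Named("n_edges") = nedges,
                            Rcpp::Named("converged") = convs);
}
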