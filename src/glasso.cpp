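// Graphical lasso by block coordinate descent (Friedman et al. algorithm):
// estimate a sparse precision matrix Theta maximising
//   log det Theta - tr(S Theta) - rho ||Theta||_1.
// Each column subproblem is an L1 regression solved on the Gram matrix by
// cyclic coordinate descent.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void lasso_gram(const mat& V, const vec& u, double rho,
                       int maxit, double tol, vec& b) {
  const int p = u.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (int k = 0; k < p; ++k) {
      const double bk = b(k);
      // gradient of the smooth part with coordinate k removed
      const double g = u(k) - dot(V.col(k), b) + V(k, k) * bk;
      double bnew = 0.0;
      if (g > rho)       bnew = (g - rho) / V(k, k);
      else if (g < -rho) bnew = (g + rho) / V(k, k);
      if (bnew != bk) {
        b(k) = bnew;
        const double d = std::fabs(bnew - bk);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < tol) break;
  }
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      int maxit = 100, double tol = 1e-4) {
  const int p = S.n_rows;
  mat W = S + rho * eye(p, p);
  mat B(p - 1, p, fill::zeros);
  const double thr = tol * mean(abs(vectorise(S - diagmat(S.diag()))));
  double dmean = datum::inf;
  bool converged = false;
  uvec all = regspace<uvec>(0, p - 1);
  for (int it = 0; it < maxit; ++it) {
    dmean = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j); s12.shed_row(j);
      vec b = B.col(j);
      lasso_gram(W11, s12, rho, 200, tol * 0.1, b);
      B.col(j) = b;
      vec w12 = W11 * b;
      vec old = W.col(j); old.shed_row(j);
      dmean += mean(abs(w12 - old));
      for (int k = 0, r = 0; k < p; ++k) {
        if (k == j) continue;
        W(k, j) = w12(r);
        W(j, k) = w12(r);
        ++r;
      }
    }
    dmean /= p;
    if (dmean < thr) { converged = true; break; }
  }
  // recover Theta from W and the regression coefficients
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx = find(all != (unsigned) j);
    vec b = B.col(j);
    vec w12 = W.col(j); w12.shed_row(j);
    const double t22 = 1.0 / (W(j, j) - dot(w12, b));
    Theta(j, j) = t22;
    for (int k = 0, r = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -b(r) * t22;
      ++r;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("crit") = dmean);
}
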