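// eLORETA fixed-point iteration and CSD kernel application.
//
// The weighted minimum-norm family solves J = W^-1 K^T (K W^-1 K^T + a H)^+ b.
// eLORETA chooses per-source symmetric 3x3 weight blocks W_i as the fixed
// point of  W_i = [ K_i^T (K W^-1 K^T + a H)^+ K_i ]^(1/2),
// which gives the estimator its exact localization property for single point
// sources in the noise-free case.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Symmetric pseudo-inverse with a relative eigenvalue floor (handles the
// average-reference rank deficiency).
static mat pinv_sym(const mat& A, double rtol = 1e-12) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, symmatu(A));
  const double mx = eval.max();
  vec inv_eval(eval.n_elem, fill::zeros);
  for (uword i = 0; i < eval.n_elem; ++i) {
    if (eval(i) > rtol * mx) inv_eval(i) = 1.0 / eval(i);
  }
  return evec * diagmat(inv_eval) * evec.t();
}

// Symmetric PSD square root (eigenvalues clamped at zero).
static mat sqrt_sym(const mat& B) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, symmatu(B));
  for (uword i = 0; i < eval.n_elem; ++i) {
    eval(i) = eval(i) > 0 ? std::sqrt(eval(i)) : 0.0;
  }
  return evec * diagmat(eval) * evec.t();
}

// C = K blockdiag(Winv) K^T for 3x3 blocks.
static mat gram_blockdiag(const mat& K, const cube& Winv) {
  const uword S = Winv.n_slices;
  mat T(K.n_rows, K.n_cols);
  for (uword s = 0; s < S; ++s) {
    T.cols(3 * s, 3 * s + 2) = K.cols(3 * s, 3 * s + 2) * Winv.slice(s);
  }
  return T * K.t();
}

// [[Rcpp::export]]
Rcpp::List eloreta_fit_cpp(const arma::mat& K, double alpha, double tol,
                           int max_iter) {
  const uword m = K.n_rows;
  if (K.n_cols % 3 != 0) Rcpp::stop("leadfield column count must be 3 * n_sources");
  const uword S = K.n_cols / 3;

  const mat H = eye(m, m) - ones(m, m) / (double)m;  // centering operator

  cube W(3, 3, S), Winv(3, 3, S);
  W.each_slice() = eye(3, 3);
  Winv.each_slice() = eye(3, 3);

  std::vector<double> relch;
  bool converged = false;
  int it = 0;
  mat Minv(m, m);

  for (it = 0; it < max_iter; ++it) {
    mat C = gram_blockdiag(K, Winv);
    const double aeff = alpha * trace(C) / (double)m;
    Minv = pinv_sym(C + aeff * H);

    double mx = 0.0;
    mat MK = Minv * K;  // m x 3S
    for (uword s = 0; s < S; ++s) {
      mat B = K.cols(3 * s, 3 * s + 2).t() * MK.cols(3 * s, 3 * s + 2);
      mat Ws = sqrt_sym(B);
      const double rel = norm(Ws - W.slice(s), "fro") /
                         std::max(norm(W.slice(s), "fro"), 1e-300);
      if (rel > mx) mx = rel;
      W.slice(s) = Ws;
      Winv.slice(s) = pinv_sym(Ws, 1e-12);
    }
    relch.push_back(mx);
    if (mx < tol) { converged = true; ++it; break; }
  }

  // resolvent consistent with the final weights
  mat C = gram_blockdiag(K, Winv);
  const double aeff = alpha * trace(C) / (double)m;
  Minv = pinv_sym(C + aeff * H);
  mat kernel(3 * S, m);
  for (uword s = 0; s < S; ++s) {
    kernel.rows(3 * s, 3 * s + 2) =
        Winv.slice(s) * K.cols(3 * s, 3 * s + 2).t() * Minv;
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = W,
      Rcpp::Named("kernel") = kernel,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("rel_changes") = relch);
}

// Current source density (per-source 3-vector norm) of kernel * data.
// [[Rcpp::export]]
arma::mat csd_epoch_cpp(const arma::mat& kernel, const arma::mat& data) {
  if (kernel.n_cols != data.n_rows) Rcpp::stop("dimension mismatch");
  const uword S = kernel.n_rows / 3;
  mat J = kernel * data;  // 3S x T
  mat out(S, data.n_cols);
  for (uword s = 0; s < S; ++s) {
    out.row(s) = sqrt(sum(square(J.rows(3 * s, 3 * s + 2)), 0));
  }
  return out;
}
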