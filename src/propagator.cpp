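// Numerical kernels for the electronic subsystem: Hermitian diagonalization
// and the substepped short-time propagator used between nuclear steps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Eigendecomposition of a complex Hermitian matrix, eigenvalues ascending.
// [[Rcpp::export(name = ".cx_eig_sym")]]
Rcpp::List cx_eig_sym(const arma::cx_mat& H) {
  vec eval;
  cx_mat evec;
  if (!eig_sym(eval, evec, H)) {
    Rcpp::stop("Hermitian eigendecomposition failed");
  }
  return Rcpp::List::create(Rcpp::Named("values") = eval,
                            Rcpp::Named("vectors") = evec);
}

// Accumulated unitary over one nuclear step: the Hamiltonian is linearly
// interpolated between H0 and H1 and treated as constant over each of the
// nsub electronic substeps (midpoint value), each advanced by its exact
// matrix exponential exp(-i H dt_sub) (hbar = 1, atomic units).
// [[Rcpp::export(name = ".cx_step_propagator")]]
arma::cx_mat cx_step_propagator(const arma::cx_mat& H0, const arma::cx_mat& H1,
                                double dt, int nsub) {
  if (nsub < 1) Rcpp::stop("nsub must be >= 1");
  const double dts = dt / nsub;
  const uword n = H0.n_rows;
  cx_mat P(n, n, fill::eye);
  vec eval;
  cx_mat evec;
  const cx_mat dH = H1 - H0;
  for (int k = 0; k < nsub; ++k) {
    const double f = (k + 0.5) / nsub;
    cx_mat Hm = H0 + f * dH;
    if (!eig_sym(eval, evec, Hm)) Rcpp::stop("eig_sym failed in propagator");
    cx_vec ph = exp(cx_double(0.0, -1.0) * conv_to<cx_vec>::from(eval) * dts);
    P = evec * diagmat(ph) * evec.t() * P;
  }
  return P;
}
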