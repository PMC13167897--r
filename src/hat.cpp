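// Dense kernels for the boosting hat-matrix recursion
//   B_m = B_{m-1} + nu W H (I - B_{m-1}).
// The matrix is held transposed (C = t(B)); transposing the recursion gives
//   C <- C + nu (I - C) H W,
// which updates whole columns of C (column-major friendly). The update is
// memory-bandwidth-bound, so C is kept in single precision behind an
// external pointer; each kernel returns trace(C) = trace(B) as a double.
// The double-precision R reference implementation in R/hat.R is the oracle
// the tests compare against.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
SEXP hat_alloc_cpp(int N) {
  fmat* C = new fmat(N, N, fill::zeros);
  Rcpp::XPtr<fmat> p(C, true);
  return p;
}

// Selected-term step with q design columns X (N x q):
//   C += nu (I - C) X (X^T X)^{-1} (W X)^T.
// [[Rcpp::export]]
double hat_term_cpp(SEXP ptr, const arma::vec& w, const arma::mat& X,
                    double nu) {
  Rcpp::XPtr<fmat> p(ptr);
  fmat& C = *p;
  fmat Xf = conv_to<fmat>::from(X);
  fvec wf = conv_to<fvec>::from(w);
  fmat V = Xf - C * Xf;                    // (I - C) X
  fmat A = Xf.t() * Xf;
  fmat WX = Xf.each_col() % wf;
  fmat T;
  if (!solve(T, A, WX.t(), solve_opts::likely_sympd)) {
    Rcpp::stop("singular design cross-product in hat-matrix update");
  }
  C += (float)nu * (V * T);
  return (double)trace(C);
}

// Optional baseline composition: H is the projection onto the per-time
// indicator columns (risk-set means by time group); grp is the 1-based time
// index of each pseudo-observation, subject-major.
// [[Rcpp::export]]
double hat_gamma_cpp(SEXP ptr, const arma::vec& w, const arma::ivec& grp,
                     int S, double nu) {
  Rcpp::XPtr<fmat> p(ptr);
  fmat& C = *p;
  const uword N = C.n_rows;
  fvec wf = conv_to<fvec>::from(w);

  fvec cnt(S, fill::zeros);
  for (uword k = 0; k < N; k++) cnt(grp(k) - 1) += 1.0f;

  // F = (E - C E) D^{-1}: column g of C E sums C's columns in group g
  fmat F(N, S, fill::zeros);
  for (uword k = 0; k < N; k++) F.col(grp(k) - 1) -= C.col(k);
  for (uword k = 0; k < N; k++) F(k, grp(k) - 1) += 1.0f;
  for (int g = 0; g < S; g++) if (cnt(g) > 0) F.col(g) /= cnt(g);

  for (uword k = 0; k < N; k++) {
    if (wf(k) != 0.0f) C.col(k) += ((float)nu * wf(k)) * F.col(grp(k) - 1);
  }
  return (double)trace(C);
}
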