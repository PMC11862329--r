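// Numerical stochastic-elasticity machinery.
//
// The per-element variance perturbation requires one full re-projection of
// the population through the kernel sequence for every kernel element with
// nonzero temporal variance (n_mesh^2 re-projections per sequence), which is
// the hot loop of a landscape sweep; it lives here in compiled code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Stochastic growth rate of n0 projected through A, with an optional
// time-varying additive adjustment d(t) applied to element (pi, pj).
// Equivalent to projecting through kernels whose (pi, pj) element series is
// A(pi,pj,t) + d(t); the full perturbed sequence is never materialized.
static double lambda_s_core(const cube& A, const vec& n0, int burn_in,
                            int pi, int pj, const vec& d) {
  const int T = A.n_slices;
  vec n = n0 / accu(n0);
  double acc = 0.0;
  int cnt = 0;
  for (int t = 0; t < T; ++t) {
    vec v = A.slice(t) * n;
    if (pi >= 0) v(pi) += d(t) * n(pj);
    double s = accu(v);
    if (!std::isfinite(s) || s <= 0.0)
      Rcpp::stop("degenerate trajectory (total reached 0) at step %d", t + 1);
    if (t + 1 > burn_in) { acc += std::log(s); ++cnt; }
    n = v / s;
  }
  if (cnt == 0) Rcpp::stop("burn_in must be < sequence length");
  return std::exp(acc / cnt);
}

// [[Rcpp::export(name = ".lambda_s_cpp")]]
double lambda_s_cpp(const arma::cube& A, const arma::vec& n0, int burn_in) {
  return lambda_s_core(A, n0, burn_in, -1, -1, vec());
}

// Per-element stochastic elasticities of variance.
//
// A: full kernel sequence (n x n x T). S: the series whose temporal variance
// is perturbed — S = A for whole-kernel elasticities, S = P or S = F for
// subkernel elasticities (the other subkernel's series stay fixed because
// the adjustment d(t) is built from S alone while projection runs through A).
//
// For each element (i,j) with sample variance of S(i,j,.) above var_tol:
//   d(t)      = (sqrt(1 + delta) - 1) * (S(i,j,t) - mean_t S(i,j,.))
//   lambda_s* = growth rate with element (i,j) adjusted by d(t)
//   E(i,j)    = (var / lambda_s) * (lambda_s* - lambda_s) / (delta * var)
// Elements with negligible variance contribute exactly 0 (the perturbation
// is a no-op there). Uses common random numbers: every perturbed projection
// consumes the same kernels and the same n0 as the unperturbed one.
//
// [[Rcpp::export(name = ".elasticity_sweep_cpp")]]
Rcpp::List elasticity_sweep_cpp(const arma::cube& A, const arma::cube& S,
                                const arma::vec& n0, int burn_in,
                                double delta, double var_tol,
                                bool keep_perturbed) {
  const int n = A.n_rows;
  const int T = A.n_slices;
  if ((int)S.n_rows != n || (int)S.n_cols != (int)A.n_cols ||
      (int)S.n_slices != T)
    Rcpp::stop("S dimensions must match A");
  if (delta <= 0.0) Rcpp::stop("delta must be > 0");
  if (T < 2) Rcpp::stop("need T >= 2 for variance computation");

  const double lam_s = lambda_s_core(A, n0, burn_in, -1, -1, vec());
  const double cscale = std::sqrt(1.0 + delta) - 1.0;

  mat E(n, A.n_cols, fill::zeros);
  mat lam_pert(n, A.n_cols);
  lam_pert.fill(datum::nan);
  int n_negative = 0;
  vec d(T);

  for (uword j = 0; j < A.n_cols; ++j) {
    Rcpp::checkUserInterrupt();
    for (uword i = 0; i < (uword)n; ++i) {
      vec s = vectorise(S.tube(i, j));
      double m = mean(s);
      double v = var(s);  // sample variance, n-1 denominator
      if (!(v > var_tol)) continue;
      d = cscale * (s - m);
      if (s.min() >= 0.0 && (s + d).min() < 0.0) ++n_negative;
      double lam_star = lambda_s_core(A, n0, burn_in, (int)i, (int)j, d);
      E(i, j) = (v / lam_s) * ((lam_star - lam_s) / (delta * v));
      if (keep_perturbed) lam_pert(i, j) = lam_star;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("E") = E,
    Rcpp::Named("lambda_s") = lam_s,
    Rcpp::Named("lambda_s_pert") = lam_pert,
    Rcpp::Named("n_negative") = n_negative);
}
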