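// Dense two-phase primal simplex for the small LPs arising from toy and
// mid-size stoichiometric models.  Solves
//     min c'x   s.t.  A x = b,  x >= 0
// with Bland's anti-cycling rule (smallest-index entering variable,
// smallest-basis-index tie break in the ratio test), which also makes the
// returned vertex deterministic across runs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PIVOT_TOL = 1e-9;
static const double COST_TOL  = 1e-9;
static const double FEAS_TOL  = 1e-7;

static void pivot_on(mat &T, vec &d, double &obj, uvec &basis,
                     unsigned r, unsigned j) {
  T.row(r) /= T(r, j);
  for (unsigned i = 0; i < T.n_rows; ++i) {
    if (i != r && std::abs(T(i, j)) > 0.0)
      T.row(i) -= T(i, j) * T.row(r);
  }
  obj -= d(j) * T(r, T.n_cols - 1);
  d   -= d(j) * T.row(r).head(d.n_elem).t();
  basis(r) = j;
}

// One simplex phase: minimize d'x given current tableau/basis.  `allowed`
// masks columns permitted to enter the basis.  Returns 0 optimal,
// 2 unbounded, 3 iteration cap hit.
static int run_phase(mat &T, vec &d, double &obj, uvec &basis,
                     const std::vector<bool> &allowed, unsigned max_iter) {
  const unsigned m = T.n_rows, ncol = d.n_elem, rhs = T.n_cols - 1;
  for (unsigned iter = 0; iter < max_iter; ++iter) {
    // Bland: smallest-index column with negative reduced cost.
    int enter = -1;
    for (unsigned j = 0; j < ncol; ++j) {
      if (allowed[j] && d(j) < -COST_TOL) { enter = (int)j; break; }
    }
    if (enter < 0) return 0;
    // Ratio test; ties broken by smallest basis index.
    int leave = -1;
    double best = datum::inf;
    for (unsigned i = 0; i < m; ++i) {
      double a = T(i, enter);
      if (a > PIVOT_TOL) {
        double ratio = T(i, rhs) / a;
        if (ratio < best - 1e-12 ||
            (ratio < best + 1e-12 &&
             (leave < 0 || basis(i) < basis(leave)))) {
          best = ratio; leave = (int)i;
        }
      }
    }
    if (leave < 0) return 2;
    pivot_on(T, d, obj, basis, (unsigned)leave, (unsigned)enter);
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_core")]]
Rcpp::List simplex_core(const arma::mat &A, const arma::vec &b,
                        const arma::vec &c, int max_iter = 200000) {
  const unsigned m = A.n_rows, n = A.n_cols;
  // Tableau [A | I_artificial | b] with b >= 0 enforced by row sign flips.
  mat T(m, n + m + 1, fill::zeros);
  T.cols(0, n - 1) = A;
  T.col(n + m) = b;
  for (unsigned i = 0; i < m; ++i) {
    if (T(i, n + m) < 0) T.row(i) *= -1.0;
    T(i, n + i) = 1.0;
  }
  uvec basis(m);
  for (unsigned i = 0; i < m; ++i) basis(i) = n + i;

  // Phase 1: minimize the sum of artificials.
  vec d(n + m, fill::zeros);
  double obj = 0.0;
  for (unsigned i = 0; i < m; ++i) {
    d.head(n) -= T.row(i).head(n).t();
    obj       -= T(i, n + m);
  }
  std::vector<bool> allowed(n + m, true);
  int st = run_phase(T, d, obj, basis, allowed, (unsigned)max_iter);
  if (st == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3);
  double art_sum = -obj; // phase-1 objective value
  if (art_sum > FEAS_TOL)
    return Rcpp::List::create(Rcpp::Named("status") = 1);

  // Drive any residual artificials (basic at zero) out of the basis.
  for (unsigned i = 0; i < m; ++i) {
    if (basis(i) >= n) {
      int j_ok = -1;
      for (unsigned j = 0; j < n; ++j)
        if (std::abs(T(i, j)) > PIVOT_TOL) { j_ok = (int)j; break; }
      if (j_ok >= 0) pivot_on(T, d, obj, basis, i, (unsigned)j_ok);
      // else: redundant row, artificial stays basic at value 0
    }
  }

  // Phase 2: real costs; artificial columns barred from entering.
  vec d2(n + m, fill::zeros);
  d2.head(n) = c;
  double obj2 = 0.0;
  for (unsigned i = 0; i < m; ++i) {
    unsigned bi = basis(i);
    if (bi < n && std::abs(c(bi)) > 0.0) {
      d2   -= c(bi) * T.row(i).head(n + m).t();
      obj2 += c(bi) * T(i, n + m);
    }
  }
  obj2 = -obj2; // stored negated so pivot_on's update convention applies
  for (unsigned j = n; j < n + m; ++j) allowed[j] = false;
  st = run_phase(T, d2, obj2, basis, allowed, (unsigned)max_iter);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = st);

  vec x(n, fill::zeros);
  for (unsigned i = 0; i < m; ++i)
    if (basis(i) < n) x(basis(i)) = T(i, n + m);
  return Rcpp::List::create(
    Rcpp::Named("status") = 0,
    Rcpp::Named("x") = x,
    Rcpp::Named("objective") = dot(c, x));
}
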