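// Dense bounded-variable primal simplex for the small linear programs that
// arise in flux variability / thermodynamics-based flux analysis on reduced
// metabolic networks (tens to a few hundred variables).  Two-phase method
// with explicit basis inverse, periodic refactorisation, and Bland's rule
// as an anti-cycling fallback.  All variable bounds must be finite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double TOL = 1e-9;       // reduced-cost / feasibility tolerance
const double PIVOT_TOL = 1e-10;

struct SimplexState {
  mat A;            // m x n constraint matrix (includes artificials)
  vec b;
  vec lb, ub;
  vec c;            // current-phase objective
  uvec basis;       // m basic variable indices
  ivec nb_at;       // per variable: -1 at lower, +1 at upper, 0 basic
  mat Binv;         // explicit basis inverse
  vec xB;           // values of basic variables
  int m, n;
};

void refactorize(SimplexState &S) {
  mat B(S.m, S.m);
  for (int i = 0; i < S.m; ++i) B.col(i) = S.A.col(S.basis[i]);
  S.Binv = inv(B);
  vec rhs = S.b;
  for (int j = 0; j < S.n; ++j) {
    if (S.nb_at[j] == -1) rhs -= S.A.col(j) * S.lb[j];
    else if (S.nb_at[j] == 1) rhs -= S.A.col(j) * S.ub[j];
  }
  S.xB = S.Binv * rhs;
}

// One phase of the simplex method on state S with objective S.c.
// Returns 0 optimal, 3 iteration limit.
int simplex_phase(SimplexState &S, int max_iter) {
  int since_refac = 0;
  for (int iter = 0; iter < max_iter; ++iter) {
    bool bland = iter > max_iter / 2;  // fallback if slow convergence
    if (++since_refac >= 60) { refactorize(S); since_refac = 0; }

    vec cB(S.m);
    for (int i = 0; i < S.m; ++i) cB[i] = S.c[S.basis[i]];
    vec y = S.Binv.t() * cB;

    // pricing: pick entering variable
    int enter = -1;
    double best = -TOL;
    int dir = 0;  // +1 increase from lower, -1 decrease from upper
    for (int j = 0; j < S.n; ++j) {
      if (S.nb_at[j] == 0) continue;
      double dj = S.c[j] - dot(y, S.A.col(j));
      if (S.nb_at[j] == -1 && dj < -TOL) {
        if (bland) { enter = j; dir = +1; break; }
        if (dj < best) { best = dj; enter = j; dir = +1; }
      } else if (S.nb_at[j] == 1 && dj > TOL) {
        if (bland) { enter = j; dir = -1; break; }
        if (-dj < best) { best = -dj; enter = j; dir = -1; }
      }
    }
    if (enter < 0) return 0;  // optimal

    vec d = S.Binv * S.A.col(enter);      // column in current basis
    // ratio test: entering moves by t*dir; basics change by -dir*t*d
    double tmax = S.ub[enter] - S.lb[enter];  // bound-flip distance
    int leave = -1;       // index into basis
    int leave_bound = 0;  // -1 leaves at lower, +1 at upper
    for (int i = 0; i < S.m; ++i) {
      double di = dir * d[i];
      int bi = S.basis[i];
      if (di > PIVOT_TOL) {  // basic decreases toward its lower bound
        double t = (S.xB[i] - S.lb[bi]) / di;
        if (t < tmax) { tmax = t; leave = i; leave_bound = -1; }
      } else if (di < -PIVOT_TOL) {  // basic increases toward upper
        double t = (S.xB[i] - S.ub[bi]) / di;
        if (t < tmax) { tmax = t; leave = i; leave_bound = +1; }
      }
    }
    if (tmax < 0) tmax = 0;

    if (leave < 0) {
      // bound flip: entering travels to its opposite bound
      S.nb_at[enter] = (dir > 0) ? 1 : -1;
      for (int i = 0; i < S.m; ++i) S.xB[i] -= dir * tmax * d[i];
      continue;
    }

    // pivot: entering becomes basic, leaving goes to a bound
    int bleave = S.basis[leave];
    double enter_val = (dir > 0 ? S.lb[enter] : S.ub[enter]) + dir * tmax;
    for (int i = 0; i < S.m; ++i) S.xB[i] -= dir * tmax * d[i];
    S.nb_at[bleave] = leave_bound;
    S.basis[leave] = enter;
    S.nb_at[enter] = 0;
    // rank-1 update of Binv
    double piv = d[leave];
    if (std::abs(piv) < PIVOT_TOL) { refactorize(S); since_refac = 0; continue; }
    rowvec brow = S.Binv.row(leave) / piv;
    for (int i = 0; i < S.m; ++i) {
      if (i == leave) continue;
      S.Binv.row(i) -= d[i] * brow;
    }
    S.Binv.row(leave) = brow;
    S.xB[leave] = enter_val;
  }
  return 3;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
Rcpp::List simplex_lp_cpp(arma::vec cobj, arma::mat Aeq, arma::vec beq,
                          arma::vec lb, arma::vec ub, bool maximize,
                          int max_iter = 20000) {
  int m = Aeq.n_rows, n = Aeq.n_cols;
  if (m == 0) {
    // pure box problem: optimum at a bound
    vec x(n);
    for (int j = 0; j < n; ++j) {
      double cj = maximize ? -cobj[j] : cobj[j];
      x[j] = (cj >= 0) ? lb[j] : ub[j];
    }
    return Rcpp::List::create(Rcpp::Named("status") = 0,
                              Rcpp::Named("x") = x,
                              Rcpp::Named("objval") = dot(cobj, x));
  }

  SimplexState S;
  S.m = m;
  S.n = n + m;  // + artificials
  S.A = join_rows(Aeq, eye(m, m));
  S.b = beq;
  S.lb = join_cols(lb, zeros(m));
  S.ub = join_cols(ub, vec(m, fill::value(datum::inf)));
  S.nb_at = ivec(S.n, fill::zeros);

  // start: structurals at the finite bound of smaller magnitude
  vec r = beq;
  for (int j = 0; j < n; ++j) {
    double v = (std::abs(lb[j]) <= std::abs(ub[j])) ? lb[j] : ub[j];
    S.nb_at[j] = (v == lb[j]) ? -1 : 1;
    r -= Aeq.col(j) * v;
  }
  // orient artificial columns so their starting values are nonnegative
  for (int i = 0; i < m; ++i) if (r[i] < 0) S.A(i, n + i) = -1.0;
  S.basis = uvec(m);
  for (int i = 0; i < m; ++i) S.basis[i] = n + i;
  refactorize(S);

  // phase 1: minimize sum of artificials
  S.c = join_cols(zeros(n), ones(m));
  int st = simplex_phase(S, max_iter);
  refactorize(S);
  double art = 0;
  for (int i = 0; i < m; ++i)
    if (S.basis[i] >= (unsigned)n) art += std::abs(S.xB[i]);
  for (int j = n; j < S.n; ++j)
    if (S.nb_at[j] == 1) art += 1e30;  // artificial stuck at +inf: impossible
  if (st == 3 || art > 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("objval") = NA_REAL);

  // fix artificials to zero for phase 2
  for (int j = n; j < S.n; ++j) S.ub[j] = 0.0;
  S.c = join_cols(maximize ? vec(-cobj) : cobj, zeros(m));
  st = simplex_phase(S, max_iter);
  refactorize(S);

  vec x(n);
  for (int j = 0; j < n; ++j) {
    if (S.nb_at[j] == -1) x[j] = lb[j];
    else if (S.nb_at[j] == 1) x[j] = ub[j];
  }
  for (int i = 0; i < m; ++i)
    if (S.basis[i] < (unsigned)n) x[S.basis[i]] = S.xB[i];
  // clamp tiny bound violations from roundoff
  for (int j = 0; j < n; ++j) {
    if (x[j] < lb[j]) x[j] = lb[j];
    if (x[j] > ub[j]) x[j] = ub[j];
  }
  double obj = dot(cobj, x);
  return Rcpp::List::create(Rcpp::Named("status") = st == 0 ? 0 : 3,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objval") = obj);
}
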