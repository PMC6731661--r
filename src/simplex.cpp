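// Dense two-phase simplex with Bland's rule for the small flux-balance LPs.
//   min/max obj'x  s.t.  A x = b,  lb <= x <= ub  (finite bounds).
// Variables are shifted to s = x - lb; upper bounds are explicit slack rows.
// Problem sizes here are tens of variables, so a dense tableau is adequate;
// Bland's rule guarantees termination under degeneracy.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tableau {
  int nrow, ncol;              // ncol includes the rhs column
  std::vector<double> a;       // row-major
  double &at(int r, int c) { return a[(size_t)r * ncol + c]; }
};

void pivot(Tableau &T, int r, int c) {
  const double piv = T.at(r, c);
  for (int j = 0; j < T.ncol; ++j) T.at(r, j) /= piv;
  for (int i = 0; i < T.nrow; ++i) {
    if (i == r) continue;
    const double f = T.at(i, c);
    if (f == 0.0) continue;
    for (int j = 0; j < T.ncol; ++j) T.at(i, j) -= f * T.at(r, j);
  }
}

// minimise cost'z over allowed columns; returns 0 optimal, 1 unbounded
int runSimplex(Tableau &T, std::vector<int> &basis, const std::vector<double> &cost,
               const std::vector<bool> &allowed, double tol) {
  const int nc = T.ncol - 1;
  std::vector<double> zrow(nc);
  for (;;) {
    for (int j = 0; j < nc; ++j) zrow[j] = -cost[j];
    for (int i = 0; i < T.nrow; ++i) {
      const double cb = cost[basis[i]];
      if (cb == 0.0) continue;
      for (int j = 0; j < nc; ++j) zrow[j] += cb * T.at(i, j);
    }
    int enter = -1;
    for (int j = 0; j < nc; ++j) {
      if (allowed[j] && zrow[j] > tol) { enter = j; break; }  // Bland
    }
    if (enter < 0) return 0;
    int leave = -1;
    double best = 0.0;
    for (int i = 0; i < T.nrow; ++i) {
      const double aij = T.at(i, enter);
      if (aij > tol) {
        const double ratio = T.at(i, nc) / aij;
        if (leave < 0 || ratio < best - tol ||
            (ratio <= best + tol && basis[i] < basis[leave])) {
          leave = i;
          best = ratio;
        }
      }
    }
    if (leave < 0) return 1;
    pivot(T, leave, enter);
    basis[leave] = enter;
  }
}

}  // namespace

// [[Rcpp::export(name = ".simplexCpp")]]
List simplexCpp(NumericVector obj, NumericMatrix A, NumericVector b,
                NumericVector lb, NumericVector ub, bool maximize,
                double tol = 1e-9) {
  const int n = obj.size(), m = b.size();
  std::vector<double> u(n), b2(m);
  for (int j = 0; j < n; ++j) u[j] = std::max(ub[j] - lb[j], 0.0);
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int j = 0; j < n; ++j) s -= A(i, j) * lb[j];
    b2[i] = s;
  }
  const int nc = 2 * n + m;
  Tableau T;
  T.nrow = m + n;
  T.ncol = nc + 1;
  T.a.assign((size_t)T.nrow * T.ncol, 0.0);
  for (int i = 0; i < m; ++i) {
    const double sign = (b2[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) T.at(i, j) = sign * A(i, j);
    T.at(i, 2 * n + i) = 1.0;
    T.at(i, nc) = sign * b2[i];
  }
  for (int j = 0; j < n; ++j) {
    T.at(m + j, j) = 1.0;
    T.at(m + j, n + j) = 1.0;
    T.at(m + j, nc) = u[j];
  }
  std::vector<int> basis(T.nrow);
  for (int i = 0; i < m; ++i) basis[i] = 2 * n + i;
  for (int j = 0; j < n; ++j) basis[m + j] = n + j;

  std::vector<double> cost1(nc, 0.0);
  std::vector<bool> allowed(nc, true);
  for (int i = 0; i < m; ++i) {
    cost1[2 * n + i] = 1.0;
    allowed[2 * n + i] = false;
  }
  runSimplex(T, basis, cost1, allowed, tol);
  double p1 = 0.0;
  for (int i = 0; i < T.nrow; ++i) {
    if (basis[i] >= 2 * n) p1 += T.at(i, nc);
  }
  if (p1 > 1e-7) {
    return List::create(_["status"] = "infeasible", _["x"] = R_NilValue,
                        _["value"] = NA_REAL);
  }
  for (int i = 0; i < T.nrow; ++i) {
    if (basis[i] >= 2 * n) {  // pivot residual artificials out if possible
      for (int j = 0; j < 2 * n; ++j) {
        if (std::fabs(T.at(i, j)) > tol) {
          pivot(T, i, j);
          basis[i] = j;
          break;
        }
      }
    }
  }

  std::vector<double> cost2(nc, 0.0);
  for (int j = 0; j < n; ++j) cost2[j] = maximize ? -obj[j] : obj[j];
  const int st = runSimplex(T, basis, cost2, allowed, tol);
  if (st == 1) {
    return List::create(_["status"] = "unbounded", _["x"] = R_NilValue,
                        _["value"] = NA_REAL);
  }
  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = lb[j];
  for (int i = 0; i < T.nrow; ++i) {
    if (basis[i] < n) x[basis[i]] = lb[basis[i]] + T.at(i, nc);
  }
  double val = 0.0;
  for (int j = 0; j < n; ++j) val += obj[j] * x[j];
  return List::create(_["status"] = "optimal", _["x"] = x, _["value"] = val);
}
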