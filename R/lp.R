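# Thin wrapper around the compiled two-phase simplex (src/simplex.cpp).
#   max/min obj'x  s.t.  A x = b,  lb <= x <= ub  (all bounds finite).
# Correctness is pinned in the test suite against brute-force vertex
# enumeration of the flux polytope on small problems.

solveLP <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(lb) == n, length(ub) == n, nrow(A) == length(b))
  if (any(!is.finite(lb)) || any(!is.finite(ub))) stop("solveLP needs finite bounds")
  if (any(lb > ub + tol)) stop("infeasible bounds: lb > ub")
  .simplexCpp(as.numeric(obj), A, as.numeric(b), as.numeric(lb),
              as.numeric(ub), isTRUE(maximize), tol)
}
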