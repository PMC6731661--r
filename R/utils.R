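# Internal helpers shared across modules.

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic stream of sub-seeds derived from one integer seed (kept well
# below 2^31 so set.seed() always accepts them).
subSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 10007 * as.double(k)) %% 2147483629)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# weight matrix (child x parent over all nodes), bias and sigma vectors of a DBN
dbnMatrices <- function(dbn) {
  n <- dbn@nodes
  W <- matrix(0, length(n), length(n), dimnames = list(n, n))
  e <- dbn@edges
  if (nrow(e)) W[cbind(match(e$child, n), match(e$parent, n))] <- e$weight
  list(W = W, b = dbn@bias[n], sigma = dbn@sigma[n])
}

# nodes reachable from 'from' (inclusive) following parent -> child edges
reachableFrom <- function(edges, from) {
  out <- unique(from)
  repeat {
    nxt <- unique(edges$child[edges$parent %in% out])
    new <- setdiff(nxt, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

# nodes from which 'to' is reachable (inclusive)
reachingTo <- function(edges, to) {
  out <- unique(to)
  repeat {
    nxt <- unique(edges$parent[edges$child %in% out])
    new <- setdiff(nxt, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
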