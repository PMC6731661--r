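# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the LP oracle enumerates polytope vertices, the
# smoothing oracle conditions an explicitly constructed joint Gaussian, and
# the arborescence oracle enumerates all parent assignments.

# --- LP oracle: brute-force vertex enumeration for max c'v, S v = 0, lb<=v<=ub
oracleLP <- function(obj, S, lb, ub, maximize = TRUE, tol = 1e-8) {
  n <- length(obj)
  m <- nrow(S)
  best <- NULL
  bestVal <- if (maximize) -Inf else Inf
  qrS <- qr(S)
  r <- qrS$rank
  free <- n - r
  if (free < 0) free <- 0
  combs <- utils::combn(n, min(free, n), simplify = FALSE)
  if (!length(combs)) combs <- list(integer(0))
  for (nb in combs) {
    grid <- expand.grid(rep(list(c(1, 2)), length(nb)))
    if (!nrow(grid)) grid <- data.frame(row.names = 1)
    for (gi in seq_len(nrow(grid))) {
      fixed <- numeric(length(nb))
      for (j in seq_along(nb)) {
        fixed[j] <- if (grid[gi, j] == 1) lb[nb[j]] else ub[nb[j]]
      }
      basic <- setdiff(seq_len(n), nb)
      rhs <- -S[, nb, drop = FALSE] %*% fixed
      sol <- tryCatch(qr.solve(S[, basic, drop = FALSE], rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n)
      v[nb] <- fixed
      v[basic] <- sol
      if (any(v < lb - tol) || any(v > ub + tol)) next
      if (max(abs(S %*% v)) > tol) next
      val <- sum(obj * v)
      if ((maximize && val > bestVal + 1e-12) || (!maximize && val < bestVal - 1e-12)) {
        bestVal <- val
        best <- v
      }
    }
  }
  list(value = bestVal, x = best)
}

# --- joint-Gaussian smoothing oracle on a small DBN
# Builds the exact joint distribution of all (gene, slice) states over slices
# 0..n by composing the linear maps, then conditions on the evidence rows
# (gene, time, mean, sd) with standard Gaussian formulas (pseudo-inverse for
# degenerate cases). Returns mean matrix and sd matrix (genes x slices).
oracleSmoother <- function(dbn, evidence, n, knockouts = character(0)) {
  g <- dbn@nodes
  G <- length(g)
  W <- matrix(0, G, G, dimnames = list(g, g))
  e <- dbn@edges
  if (nrow(e)) W[cbind(match(e$child, g), match(e$parent, g))] <- e$weight
  b <- dbn@bias[g]
  sg <- dbn@sigma[g]
  ko <- match(knockouts, g)
  if (length(ko)) {
    W[ko, ] <- 0
    b[ko] <- 0
    sg[ko] <- 0
  }
  N <- G * (n + 1L)
  mu <- numeric(N)
  Sig <- matrix(0, N, N)
  idx <- function(t) (t * G + 1L):((t + 1L) * G)
  m0 <- dbn@initMean[g]
  P0 <- diag(dbn@initSd[g]^2, G)
  if (length(ko)) {
    m0[ko] <- 0
    P0[ko, ] <- 0
    P0[, ko] <- 0
  }
  mu[idx(0)] <- m0
  Sig[idx(0), idx(0)] <- P0
  for (t in seq_len(n)) {
    prev <- idx(t - 1L)
    cur <- idx(t)
    mu[cur] <- W %*% mu[prev] + b
    # cross-covariances with every earlier slice
    for (s in 0:(t - 1L)) {
      C <- W %*% Sig[idx(t - 1L), idx(s)]
      Sig[cur, idx(s)] <- C
      Sig[idx(s), cur] <- t(C)
    }
    Sig[cur, cur] <- W %*% Sig[prev, prev] %*% t(W) + diag(sg^2, G)
  }
  if (!is.null(evidence) && nrow(evidence)) {
    oIdx <- evidence$time * G + match(evidence$gene, g)
    H <- matrix(0, nrow(evidence), N)
    H[cbind(seq_len(nrow(evidence)), oIdx)] <- 1
    R <- diag(evidence$sd^2, nrow(evidence))
    S2 <- H %*% Sig %*% t(H) + R
    K <- Sig %*% t(H) %*% MASS::ginv(S2)
    mu <- mu + drop(K %*% (evidence$mean - drop(H %*% mu)))
    Sig <- Sig - K %*% H %*% Sig
  }
  M <- matrix(mu, G, n + 1L, dimnames = list(g, NULL))
  V <- matrix(pmax(diag(Sig), 0), G, n + 1L, dimnames = list(g, NULL))
  list(mean = M, sd = sqrt(V))
}

# --- exhaustive arborescence oracle: every non-root node picks one incoming
# edge; keep assignments that form a spanning arborescence; return the best
# total weight.
oracleArborescence <- function(graph, root) {
  nodes <- unique(c(graph$parent, graph$child, root))
  others <- setdiff(nodes, root)
  inEdges <- lapply(others, function(v) which(graph$child == v & graph$parent != v))
  if (any(vapply(inEdges, length, 0L) == 0)) return(NULL)
  best <- -Inf
  bestSet <- NULL
  recurse <- function(i, chosen) {
    if (i > length(others)) {
      par <- setNames(graph$parent[chosen], others)
      # acyclic check: walk each node to root
      for (v in others) {
        seen <- character(0)
        u <- v
        while (u != root) {
          if (u %in% seen) return(invisible(NULL))
          seen <- c(seen, u)
          u <- if (u %in% names(par)) par[[u]] else return(invisible(NULL))
        }
      }
      w <- sum(graph$weight[chosen])
      if (w > best + 1e-12) {
        best <<- w
        bestSet <<- chosen
      }
      return(invisible(NULL))
    }
    for (eidx in inEdges[[i]]) recurse(i + 1L, c(chosen, eidx))
  }
  recurse(1L, integer(0))
  if (is.null(bestSet)) NULL else list(weight = best, edges = bestSet)
}

# --- area under the precision-recall curve for an edge ranking
auprEdges <- function(ranking, trueEdges) {
  if (!nrow(ranking)) return(0)
  key <- function(df) paste(df$parent, df$child)
  lab <- key(ranking) %in% key(trueEdges)
  nPos <- nrow(trueEdges)
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / nPos
  # step-wise interpolation over recall levels reached
  sum(diff(c(0, rec)) * prec)
}

# small hand-made hybrid model: 1 regulator gating 1 enzyme on a 2-reaction
# chain (uptake then biomass), used all over the unit tests
toyChainModel <- function(uptakeUb = 10, yield = 0.5) {
  dbn <- regulatoryDBN(
    c("R1", "E1"), c("regulator", "enzyme"),
    data.frame(parent = "R1", child = "E1", weight = 1),
    bias = c(R1 = 0.8, E1 = 0), sigma = c(R1 = 0.05, E1 = 0.05),
    initMean = c(R1 = 0.8, E1 = 0.8), initSd = c(R1 = 0, E1 = 0))
  mets <- data.frame(id = c("glc_e", "glc_i"),
                     external = c(TRUE, FALSE), buffered = c(FALSE, FALSE),
                     carbon = c(6, 6))
  rx <- data.frame(id = c("UPT", "BIO", "EX_glc"),
                   lb = c(0, 0, -uptakeUb), ub = c(uptakeUb, 100, 0))
  rx$stoichiometry <- list(c(glc_e = -1, glc_i = 1),
                           setNames(-1 / yield, "glc_i"),
                           c(glc_e = -1))
  met <- metabolicModel(mets, rx, biomassId = "BIO", exchangeIds = "EX_glc",
                        geneRules = list(UPT = "E1"),
                        uptakeKinetics = data.frame(
                          metabolite = "glc_e", exchange = "EX_glc",
                          vmax = uptakeUb, km = 0.5))
  hybridModel(dbn, met)
}
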