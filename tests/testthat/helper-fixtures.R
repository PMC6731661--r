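# Shared fixtures built in code at test time.

labCfg <- function(seed = 1, ...) labConfig(seed = seed, ...)

# one small ground truth per seed, memoised across tests in a session
.truthCache <- new.env(parent = emptyenv())
cachedTruth <- function(seed = 1, ...) {
  key <- paste(seed, paste(c(...), collapse = "_"), sep = "_")
  if (is.null(.truthCache[[key]])) {
    .truthCache[[key]] <- generateGroundTruth(labConfig(seed = seed, ...))
  }
  .truthCache[[key]]
}

# stable random DBN (spectral radius < 1) for regression/recovery tests
randomStableDBN <- function(nGenes = 6, nEdges = 6, seed = 1, sigma = 0.1) {
  set.seed(seed)
  nodes <- sprintf("G%02d", seq_len(nGenes))
  nEdges <- min(nEdges, nGenes * (nGenes - 1))
  edges <- NULL
  for (k in seq_len(nEdges)) {
    repeat {
      p <- sample(nodes, 1)
      ch <- sample(setdiff(nodes, p), 1)
      if (is.null(edges) || !any(edges$parent == p & edges$child == ch)) break
    }
    edges <- rbind(edges, data.frame(parent = p, child = ch,
                                     weight = runif(1, -0.6, 0.6)))
  }
  # damp rows so the linear map is a contraction
  for (ch in unique(edges$child)) {
    rows <- edges$child == ch
    s <- sum(abs(edges$weight[rows]))
    if (s >= 0.95) edges$weight[rows] <- edges$weight[rows] * 0.9 / s
  }
  regulatoryDBN(nodes, rep("regulator", nGenes), edges,
                bias = setNames(runif(nGenes, 0.2, 0.8), nodes),
                sigma = sigma, initMean = setNames(runif(nGenes), nodes),
                initSd = 0)
}

# sample a stochastic trajectory from a DBN (data generator for fitting tests)
sampleDBNData <- function(dbn, nSlices, seed = 1) {
  set.seed(seed)
  g <- dbn@nodes
  W <- matrix(0, length(g), length(g), dimnames = list(g, g))
  e <- dbn@edges
  if (nrow(e)) W[cbind(match(e$child, g), match(e$parent, g))] <- e$weight
  M <- matrix(NA_real_, length(g), nSlices, dimnames = list(g, NULL))
  x <- dbn@initMean[g] + rnorm(length(g), 0, dbn@initSd[g])
  M[, 1] <- x
  for (t in 2:nSlices) {
    x <- drop(W %*% x) + dbn@bias[g] + rnorm(length(g), 0, dbn@sigma[g])
    M[, t] <- x
  }
  colnames(M) <- format(seq(0, by = 0.5, length.out = nSlices))
  M
}
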