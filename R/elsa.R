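#' @include dbn.R
NULL

#' Lagged dependency graph from expression data
#'
#' Builds the weighted digraph an ensemble component is grown on: every
#' candidate regulator is connected to every other gene with weight equal to
#' the absolute Pearson correlation between the parent at slice t and the
#' child at slice t + 1, over the supplied transitions. Zero-variance genes
#' get weight-0 edges (with a warning).
#'
#' @param data expression matrix, genes x ordered time points.
#' @param candidates candidate parent genes (regulator-tagged).
#' @param transitions indices of the transitions (t, t+1) to use; defaults
#'   to all consecutive pairs. Values may repeat (bootstrap).
#' @return data.frame \code{parent}, \code{child}, \code{weight}.
#' @export
dependencyGraph <- function(data, candidates, transitions = NULL) {
  geneIds <- rownames(data)
  stopifnot(all(candidates %in% geneIds))
  nT <- ncol(data) - 1L
  if (is.null(transitions)) transitions <- seq_len(nT)
  if (length(transitions) < 2) stop("need at least 2 transitions")
  X0 <- t(data[, transitions, drop = FALSE])
  X1 <- t(data[, transitions + 1L, drop = FALSE])
  sd0 <- apply(X0[, candidates, drop = FALSE], 2, stats::sd)
  sd1 <- apply(X1, 2, stats::sd)
  if (any(sd0 == 0) || any(sd1 == 0)) {
    warning("zero-variance gene(s); their edges get weight 0")
  }
  C <- suppressWarnings(abs(stats::cor(X0[, candidates, drop = FALSE], X1)))
  C[!is.finite(C)] <- 0
  out <- data.frame(
    parent = rep(candidates, times = length(geneIds)),
    child = rep(geneIds, each = length(candidates)),
    weight = as.vector(C), stringsAsFactors = FALSE)
  out[out$parent != out$child, , drop = FALSE]
}

#' Maximum spanning arborescence (Chu-Liu/Edmonds)
#'
#' Finds the spanning arborescence rooted at \code{root} that maximises
#' total edge weight. Deterministic: among equally weighted incoming edges
#' the lexicographically smallest parent id wins.
#'
#' @param graph data.frame \code{parent}, \code{child}, \code{weight}.
#' @param root root node id.
#' @return data.frame of the chosen edges (subset of \code{graph} rows).
#' @examples
#' g <- data.frame(parent = c("r", "r", "a"), child = c("a", "b", "b"),
#'                 weight = c(2, 1, 3))
#' maxArborescence(g, "r")  # keeps r->a and a->b (total 5)
#' @export
maxArborescence <- function(graph, root) {
  nodes <- unique(c(graph$parent, graph$child, root))
  reach <- reachableFrom(graph[c("parent", "child")], root)
  un <- setdiff(nodes, reach)
  if (length(un)) {
    stop("no spanning arborescence: unreachable from root: ",
         paste(sort(un), collapse = ", "))
  }
  graph$.id <- seq_len(nrow(graph))
  picked <- chuLiu(graph, nodes, root)
  out <- graph[graph$.id %in% picked, , drop = FALSE]
  out$.id <- NULL
  rownames(out) <- NULL
  out
}

# Recursive Chu-Liu/Edmonds on a graph carrying original edge ids (.id).
# Returns the original ids of the arborescence edges.
chuLiu <- function(graph, nodes, root) {
  others <- setdiff(nodes, root)
  if (!length(others)) return(integer(0))
  # best incoming edge per node (max weight, tie: smallest parent id)
  bestRow <- integer(0)
  bestFor <- list()
  for (v in others) {
    e <- graph[graph$child == v & graph$parent != v, , drop = FALSE]
    if (!nrow(e)) stop("node without incoming edge: ", v)
    e <- e[order(-e$weight, e$parent), , drop = FALSE]
    bestFor[[v]] <- e[1, ]
    bestRow <- c(bestRow, e$.id[1])
  }
  # cycle detection among picked parents
  parentOf <- vapply(bestFor, function(e) e$parent, "")
  cyc <- NULL
  for (v in others) {
    path <- character(0)
    u <- v
    while (u != root && !(u %in% path)) {
      path <- c(path, u)
      u <- if (u %in% names(parentOf)) parentOf[[u]] else root
    }
    if (u != root) {
      i <- match(u, path)
      cyc <- path[i:length(path)]
      break
    }
  }
  if (is.null(cyc)) return(bestRow)

  cid <- paste0(".cyc", length(nodes))
  inCyc <- nodes %in% cyc
  names(inCyc) <- nodes
  cycBest <- setNames(vapply(cyc, function(v) bestFor[[v]]$weight, 0), cyc)
  # contract the cycle
  g2 <- graph[!(graph$parent %in% cyc & graph$child %in% cyc), , drop = FALSE]
  enter <- g2$child %in% cyc
  g2$weight[enter] <- g2$weight[enter] - cycBest[g2$child[enter]]
  g2$.enterChild <- ifelse(enter, g2$child, NA_character_)
  g2$child[enter] <- cid
  g2$parent[g2$parent %in% cyc] <- cid
  g2 <- g2[g2$parent != g2$child, , drop = FALSE]
  # keep, per (parent, contracted-child), the best adjusted edge
  nodes2 <- c(setdiff(nodes, cyc), cid)
  sub <- chuLiu(g2, nodes2, root)
  chosen <- g2[g2$.id %in% sub, , drop = FALSE]
  entering <- chosen[chosen$child == cid, , drop = FALSE]
  keep <- chosen$.id
  # expand: drop the cycle edge into the node the entering edge points at
  dropAt <- entering$.enterChild[1]
  for (v in cyc) {
    if (!identical(v, dropAt)) keep <- c(keep, bestFor[[v]]$.id)
  }
  keep
}

#' Ensemble edge ranking over spanning arborescences
#'
#' The structure-inference workhorse: K ensemble components are grown by
#' double sampling -- a bootstrap over transitions crossed with a uniform
#' subsample of candidate parents -- and each component is the Edmonds
#' maximum spanning arborescence of its sampled dependency graph (a virtual
#' root connected to every gene with weight \code{eps} makes the arborescence
#' well defined without singling out a biological root). Components are
#' aggregated by edge frequency f(e); edges of the prior network are floored
#' at \code{priorFloor} so literature edges survive weak data; finally a
#' postfilter refits each child's incoming candidate weights on the full
#' dataset (ridge) and drops edges with |w| < \code{wMin}.
#'
#' @param data expression matrix, genes x time points.
#' @param prior optional [RegulatoryDBN-class] prior network.
#' @param K ensemble size (>= 1).
#' @param rowFrac bootstrap fraction of transitions per component.
#' @param nodeFrac fraction of candidate parents per component.
#' @param seed RNG seed.
#' @param candidates candidate parents; defaults to the prior's regulators.
#' @param priorFloor frequency floor for prior edges.
#' @param wMin postfilter coefficient threshold.
#' @param ridge ridge penalty of the postfilter fit.
#' @param eps virtual-root edge weight.
#' @return data.frame \code{parent}, \code{child}, \code{frequency},
#'   \code{weight} (mean sampled dependency weight), sorted by frequency
#'   (ties: parent then child); attributes \code{K} and \code{candidates}.
#' @export
ensembleRank <- function(data, prior = NULL, K = 200, rowFrac = 0.8,
                         nodeFrac = 0.7, seed = 1, candidates = NULL,
                         priorFloor = 0.5, wMin = 0.05, ridge = 1e-2,
                         eps = 1e-6) {
  stopifnot(K >= 1, rowFrac > 0, rowFrac <= 1, nodeFrac > 0, nodeFrac <= 1)
  if (is.null(candidates)) {
    if (is.null(prior)) stop("need either a prior network or explicit candidates")
    candidates <- regulators(prior)
  }
  candidates <- intersect(candidates, rownames(data))
  if (!length(candidates)) stop("candidate parent set is empty")
  geneIds <- rownames(data)
  nT <- ncol(data) - 1L
  root <- ".root"
  counts <- new.env(parent = emptyenv())
  withSeed(seed, {
    for (k in seq_len(K)) {
      trans <- base::sample(seq_len(nT), max(2L, round(rowFrac * nT)), replace = TRUE)
      par_k <- base::sample(candidates, max(1L, ceiling(nodeFrac * length(candidates))))
      dg <- suppressWarnings(dependencyGraph(data, sort(par_k), transitions = trans))
      dg <- rbind(dg, data.frame(parent = root, child = geneIds, weight = eps,
                                 stringsAsFactors = FALSE))
      arb <- maxArborescence(dg, root)
      arb <- arb[arb$parent != root, , drop = FALSE]
      for (i in seq_len(nrow(arb))) {
        key <- paste(arb$parent[i], arb$child[i], sep = "\r")
        cur <- counts[[key]]
        if (is.null(cur)) cur <- c(0, 0)
        counts[[key]] <- cur + c(1, arb$weight[i])
      }
    }
  })
  keys <- ls(counts)
  split2 <- strsplit(keys, "\r", fixed = TRUE)
  rank <- data.frame(
    parent = vapply(split2, `[`, "", 1L),
    child = vapply(split2, `[`, "", 2L),
    frequency = vapply(keys, function(k) counts[[k]][1] / K, 0),
    weight = vapply(keys, function(k) counts[[k]][2] / counts[[k]][1], 0),
    stringsAsFactors = FALSE)
  rownames(rank) <- NULL
  if (!is.null(prior) && nrow(dbnEdges(prior))) {
    pe <- dbnEdges(prior)
    for (i in seq_len(nrow(pe))) {
      j <- which(rank$parent == pe$parent[i] & rank$child == pe$child[i])
      if (length(j)) {
        rank$frequency[j] <- max(rank$frequency[j], priorFloor)
      } else {
        rank <- rbind(rank, data.frame(parent = pe$parent[i], child = pe$child[i],
                                       frequency = priorFloor, weight = NA_real_))
      }
    }
  }
  # postfilter: refit each child's incoming weights on the full data
  keep <- rep(TRUE, nrow(rank))
  for (ch in unique(rank$child)) {
    rows <- which(rank$child == ch)
    pa <- rank$parent[rows]
    X <- t(data[pa, 1:nT, drop = FALSE])
    y <- data[ch, 2:(nT + 1L)]
    Xp <- cbind(1, X)
    pen <- diag(c(0, rep(ridge, length(pa))), length(pa) + 1L)
    beta <- tryCatch(drop(solve(crossprod(Xp) + pen, crossprod(Xp, y))),
                     error = function(e) rep(NA_real_, length(pa) + 1L))
    keep[rows] <- is.na(beta[-1]) | abs(beta[-1]) >= wMin
  }
  rank <- rank[keep, , drop = FALSE]
  rank <- rank[order(-rank$frequency, rank$parent, rank$child), , drop = FALSE]
  rownames(rank) <- NULL
  attr(rank, "K") <- K
  attr(rank, "candidates") <- candidates
  rank
}

#' Export an edge ranking
#'
#' @param ranking output of [ensembleRank()].
#' @param path TSV path (columns parent, child, frequency, weight).
#' @export
writeEdgeRankingTSV <- function(ranking, path) {
  write.table(ranking[c("parent", "child", "frequency", "weight")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Forward selection of ranked edges by cross-validated prediction error
#'
#' Walks the edge ranking in order; each candidate edge (absent from the
#' base structure, regulator parent) is tentatively added, the child's
#' conditional refitted, and the edge kept only if the leave-one-out
#' one-step prediction error strictly decreases. Stops after
#' \code{maxAdds} accepted edges or when the ranking is exhausted. The LOO
#' error is monotone non-increasing over accepted steps by construction.
#'
#' @param base a [RegulatoryDBN-class] to extend.
#' @param ranking an edge ranking from [ensembleRank()].
#' @param data expression matrix used for refitting and validation.
#' @param maxAdds maximum number of accepted edges.
#' @param ridge ridge penalty for refits.
#' @return the refitted, possibly extended [RegulatoryDBN-class]; attribute
#'   \code{accepted} lists the added edges.
#' @export
forwardSelect <- function(base, ranking, data, maxAdds = 10, ridge = 1e-2) {
  dbn <- base
  errs <- looPredictionError(dbn, data, ridge = ridge, perNode = TRUE)
  accepted <- ranking[0, c("parent", "child")]
  for (i in seq_len(nrow(ranking))) {
    if (nrow(accepted) >= maxAdds) break
    p <- ranking$parent[i]
    ch <- ranking$child[i]
    if (!(p %in% regulators(dbn)) || !(ch %in% dbn@nodes) || p == ch) next
    if (any(dbn@edges$parent == p & dbn@edges$child == ch)) next
    cand <- dbn
    cand@edges <- rbind(cand@edges,
                        data.frame(parent = p, child = ch, weight = 0))
    newErr <- looChildError(cand, data, ch, ridge)
    # require a materially better fit (1% relative), not a numerical tie, so
    # chance fluctuations of the cross-validated error rarely add edges
    if (newErr < errs[ch] * (1 - 1e-2)) {
      dbn <- cand
      errs[ch] <- newErr
      accepted <- rbind(accepted, data.frame(parent = p, child = ch))
    }
  }
  out <- fitParameters(dbn, data, ridge = ridge)
  attr(out, "accepted") <- accepted
  out
}

# LOO error of a single child under the given structure
looChildError <- function(dbn, data, child, ridge) {
  nT <- ncol(data) - 1L
  pa <- dbn@edges$parent[dbn@edges$child == child]
  X0 <- t(data[, 1:nT, drop = FALSE])
  Xp <- cbind(rep(1, nT), if (length(pa)) X0[, pa, drop = FALSE] else NULL)
  pen <- diag(c(0, rep(ridge, length(pa))), ncol(Xp))
  A <- solve(crossprod(Xp) + pen)
  H <- Xp %*% A %*% t(Xp)
  y <- data[child, 2:(nT + 1L)]
  res <- y - drop(H %*% y)
  h <- pmin(diag(H), 1 - 1e-12)
  mean((res / (1 - h))^2)
}
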