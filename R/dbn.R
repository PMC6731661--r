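#' @include model-core.R utils.R
NULL

#' Gene-state slice helpers
#'
#' A slice is the Gaussian state of every gene at one time index: a list with
#' named numeric vectors \code{mean} and \code{sd}. \code{initialSlice()}
#' builds slice 0 from the DBN's initial-state parameters, applying knockout
#' clamps.
#'
#' @param mean,sd named numeric vectors over the same gene set.
#' @return a slice (list with \code{mean}, \code{sd}).
#' @export
geneStateSlice <- function(mean, sd) {
  stopifnot(identical(names(mean), names(sd)), all(sd >= 0))
  list(mean = mean, sd = sd)
}

#' @rdname geneStateSlice
#' @param dbn a [RegulatoryDBN-class].
#' @param knockouts deleted genes, clamped to (0, 0).
#' @export
initialSlice <- function(dbn, knockouts = character(0)) {
  m <- dbn@initMean[dbn@nodes]
  s <- dbn@initSd[dbn@nodes]
  m[knockouts] <- 0
  s[knockouts] <- 0
  geneStateSlice(m, s)
}

#' One forward step of the two-slice DBN
#'
#' Propagates per-gene Gaussian states one slice ahead under the
#' linear-Gaussian conditionals, treating genes as independent within a slice
#' (diagonal covariance): for each non-clamped gene
#' \eqn{\mu' = b + \sum_p w_p \mu_p} and
#' \eqn{{sd'}^2 = \sum_p w_p^2 sd_p^2 + \sigma^2}. Knocked-out genes stay at
#' (0, 0).
#'
#' @param dbn a [RegulatoryDBN-class].
#' @param slice a gene-state slice covering all nodes (see
#'   [geneStateSlice()]).
#' @param knockouts deleted genes.
#' @return the next slice.
#' @export
forwardStep <- function(dbn, slice, knockouts = character(0)) {
  n <- dbn@nodes
  if (!all(n %in% names(slice$mean))) {
    stop("slice does not cover all nodes: missing ",
         paste(setdiff(n, names(slice$mean)), collapse = ", "))
  }
  mats <- dbnMatrices(dbn)
  mu <- drop(mats$W %*% slice$mean[n]) + mats$b
  v <- drop((mats$W^2) %*% (slice$sd[n]^2)) + mats$sigma^2
  mu[knockouts] <- 0
  v[knockouts] <- 0
  geneStateSlice(setNames(mu, n), setNames(sqrt(v), n))
}

#' Pure regulatory forward simulation
#'
#' Chains [forwardStep()] for \code{n} steps from an initial slice, without
#' any metabolic coupling or metabolite rules (for the coupled loop see
#' [simulateStrain()]).
#'
#' @param dbn a [RegulatoryDBN-class].
#' @param init initial slice; defaults to [initialSlice()].
#' @param n number of steps (>= 1); the result has n + 1 slices.
#' @param knockouts deleted genes.
#' @param dt slice duration in hours (only sets the time stamps).
#' @return a [GeneStateTrajectory-class] tagged \code{"forward"}.
#' @export
forwardSimulate <- function(dbn, n, init = NULL, knockouts = character(0), dt = 0.5) {
  stopifnot(n >= 1)
  if (is.null(init)) init <- initialSlice(dbn, knockouts)
  g <- dbn@nodes
  M <- matrix(NA_real_, length(g), n + 1L, dimnames = list(g, paste0("t", 0:n)))
  S <- M
  M[, 1] <- init$mean[g]
  S[, 1] <- init$sd[g]
  mats <- dbnMatrices(dbn)
  koIdx <- match(knockouts, g)
  mu <- init$mean[g]
  v <- init$sd[g]^2
  for (t in seq_len(n)) {
    mu <- drop(mats$W %*% mu) + mats$b
    v <- drop((mats$W^2) %*% v) + mats$sigma^2
    if (length(koIdx)) {
      mu[koIdx] <- 0
      v[koIdx] <- 0
    }
    M[, t + 1L] <- mu
    S[, t + 1L] <- sqrt(v)
  }
  new("GeneStateTrajectory", mean = M, sd = S, times = (0:n) * dt,
      direction = "forward")
}

#' Sample a stochastic trajectory from the regulatory DBN
#'
#' Draws one realisation of the pure regulatory process: slice 0 from the
#' initial-state Gaussians, then \eqn{x_{t+1} \sim N(b + W x_t, \sigma^2)}
#' per node. No metabolic coupling or metabolite rules (for those see
#' [simulateStrain()] with \code{sample = TRUE}).
#'
#' @param dbn a [RegulatoryDBN-class].
#' @param nSlices number of slices to return (>= 2).
#' @param seed RNG seed.
#' @param knockouts deleted genes, clamped to 0.
#' @param dt slice duration in hours (column names only).
#' @return matrix genes x nSlices.
#' @export
sampleTrajectory <- function(dbn, nSlices, seed = NULL,
                             knockouts = character(0), dt = 0.5) {
  stopifnot(nSlices >= 2)
  g <- dbn@nodes
  mats <- dbnMatrices(dbn)
  koIdx <- match(knockouts, g)
  withSeed(seed, {
    M <- matrix(NA_real_, length(g), nSlices,
                dimnames = list(g, format((seq_len(nSlices) - 1) * dt)))
    x <- dbn@initMean[g] + rnorm(length(g), 0, dbn@initSd[g])
    if (length(koIdx)) x[koIdx] <- 0
    M[, 1] <- x
    for (t in 2:nSlices) {
      x <- drop(mats$W %*% x) + mats$b + rnorm(length(g), 0, mats$sigma)
      if (length(koIdx)) x[koIdx] <- 0
      M[, t] <- x
    }
    M
  })
}

#' Fit DBN parameters to expression data by ridge regression
#'
#' With the structure fixed, each node's bias and incoming weights minimise
#' the penalised one-step squared error
#' \eqn{\sum_t (x_{g,t+1} - b - \sum_p w_p x_{p,t})^2 + \lambda \|w\|^2}
#' (the intercept is not penalised); \eqn{\sigma_g} is set to the residual SD
#' (maximum-likelihood, denominator n). Deterministic given the data.
#'
#' @param structure a [RegulatoryDBN-class] providing nodes and edges.
#' @param data expression matrix, genes x ordered time points (see
#'   [readExpressionTSV()]); must cover all nodes.
#' @param ridge penalty \eqn{\lambda \ge 0} (default 1e-2).
#' @return the DBN with refitted \code{bias}, edge weights and \code{sigma};
#'   initial states are set to the first data column (SD 0).
#' @export
fitParameters <- function(structure, data, ridge = 1e-2) {
  stopifnot(ridge >= 0)
  g <- structure@nodes
  if (!all(g %in% rownames(data))) {
    stop("expression data does not cover nodes: ",
         paste(setdiff(g, rownames(data)), collapse = ", "))
  }
  nT <- ncol(data) - 1L
  if (nT < 1L) stop("need at least 2 consecutive time points")
  X0 <- t(data[g, 1:nT, drop = FALSE])          # transitions x genes (time t)
  X1 <- t(data[g, 2:(nT + 1L), drop = FALSE])   # time t+1
  edges <- structure@edges
  bias <- structure@bias
  sigma <- structure@sigma
  for (child in g) {
    pa <- edges$parent[edges$child == child]
    p <- length(pa)
    if (p == 0L) {
      bias[child] <- mean(X1[, child])
      sigma[child] <- sqrt(mean((X1[, child] - bias[child])^2))
      next
    }
    if (ridge == 0 && nT < p + 1L) {
      stop("singular fit for '", child, "': ", nT, " transitions for ",
           p + 1L, " parameters with ridge = 0")
    }
    Xp <- cbind(1, X0[, pa, drop = FALSE])
    pen <- diag(c(0, rep(ridge, p)), p + 1L)
    beta <- tryCatch(solve(crossprod(Xp) + pen, crossprod(Xp, X1[, child])),
                     error = function(e) stop("singular fit for '", child, "': ",
                                              conditionMessage(e), call. = FALSE))
    bias[child] <- beta[1]
    for (k in seq_along(pa)) {
      edges$weight[edges$child == child & edges$parent == pa[k]] <- beta[k + 1L]
    }
    res <- X1[, child] - Xp %*% beta
    sigma[child] <- sqrt(mean(res^2))
  }
  out <- structure
  out@edges <- edges
  out@bias <- bias
  out@sigma <- sigma
  out@initMean <- setNames(data[g, 1], g)
  out@initSd <- setNames(rep(0, length(g)), g)
  validObject(out)
  out
}

#' Leave-one-out one-step prediction error
#'
#' Mean squared one-step-ahead prediction error over held-out transitions:
#' each transition is predicted from a model refitted (same ridge penalty) on
#' the remaining transitions. Computed exactly per node through the ridge
#' leave-one-out identity \eqn{e_i^{loo} = e_i / (1 - h_{ii})} with \eqn{H}
#' the penalised hat matrix, which equals explicit refitting fold by fold.
#' Deterministic; fold order is the time order.
#'
#' @inheritParams fitParameters
#' @param dbn a [RegulatoryDBN-class] whose structure is evaluated.
#' @param perNode return the per-node error vector instead of the mean.
#' @return mean (or per-node) squared LOO prediction error.
#' @export
looPredictionError <- function(dbn, data, ridge = 1e-2, perNode = FALSE) {
  g <- dbn@nodes
  nT <- ncol(data) - 1L
  if (nT < 3L) stop("need at least 3 transitions for leave-one-out")
  X0 <- t(data[g, 1:nT, drop = FALSE])
  X1 <- t(data[g, 2:(nT + 1L), drop = FALSE])
  edges <- dbn@edges
  errs <- setNames(numeric(length(g)), g)
  for (child in g) {
    pa <- edges$parent[edges$child == child]
    Xp <- cbind(rep(1, nT), if (length(pa)) X0[, pa, drop = FALSE] else NULL)
    pen <- diag(c(0, rep(ridge, length(pa))), ncol(Xp))
    A <- tryCatch(solve(crossprod(Xp) + pen),
                  error = function(e) stop("singular fit for '", child, "'", call. = FALSE))
    H <- Xp %*% A %*% t(Xp)
    y <- X1[, child]
    res <- y - H %*% y
    h <- pmin(diag(H), 1 - 1e-12)
    errs[child] <- mean((res / (1 - h))^2)
  }
  if (perNode) errs else mean(errs)
}

#' Read / write expression matrices
#'
#' Tab-separated layout: first column gene id, remaining columns ordered
#' time-point samples, header row carrying the time stamps in hours (e.g.
#' \code{gene  0  0.5  1.0 ...}).
#'
#' @param path TSV file path.
#' @return \code{readExpressionTSV}: numeric matrix genes x time points with
#'   a \code{times} attribute (hours parsed from the header).
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "times") <- suppressWarnings(as.numeric(colnames(m)))
  m
}

#' @rdname readExpressionTSV
#' @param mat genes x time points matrix; column names are the time stamps.
#' @export
writeExpressionTSV <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
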