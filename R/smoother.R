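#' @include dbn.R
NULL

#' Backward inference of gene states from partial evidence
#'
#' Conditions the linear-Gaussian DBN on Gaussian observations of a subset of
#' (gene, time) pairs -- typically enzyme-gene evidence derived from observed
#' growth via [boundsFromGrowth()] -- and returns the smoothed posterior
#' (mean, SD) for every gene at every slice. The whole gene vector is treated
#' as the state of a linear-Gaussian state-space model and smoothed exactly by
#' Kalman filtering plus Rauch-Tung-Striebel backward recursion, so within the
#' evidence-relevant subgraph the posterior is the exact joint-Gaussian
#' conditional; genes with no path to any evidence keep their forward prior.
#' Degenerate (zero-variance) directions are handled with pseudo-inverses, so
#' exact evidence and deterministic nodes are permitted.
#'
#' @param dbn a [RegulatoryDBN-class].
#' @param evidence data.frame with columns \code{gene}, \code{time} (slice
#'   index, 0-based), \code{mean}, \code{sd} (observation noise SD, >= 0).
#'   May have zero rows, in which case the result equals [forwardSimulate()].
#' @param n number of steps; slices 0..n are returned.
#' @param knockouts deleted genes, clamped to (0, 0).
#' @param init optional initial slice (defaults to the DBN's initial state).
#' @param dt slice duration (hours), for the time stamps only.
#' @param clamps optional data.frame \code{gene}, \code{time}, \code{mean},
#'   \code{sd}: states overwritten by metabolite rules during the coupled
#'   simulation. Clamps are part of the dynamics, not evidence: at the
#'   clamped slice the gene's state is redrawn as N(mean, sd^2) independent
#'   of its past, exactly as the rule acts in [simulateStrain()], so the
#'   smoothed posterior of an unobserved model matches the hybrid forward
#'   trajectory.
#' @return a [GeneStateTrajectory-class] tagged \code{"backward"}.
#' @export
backwardInfer <- function(dbn, evidence, n, knockouts = character(0),
                          init = NULL, dt = 0.5, clamps = NULL) {
  g <- dbn@nodes
  G <- length(g)
  if (is.null(evidence) || !nrow(evidence)) {
    evidence <- data.frame(gene = character(0), time = integer(0),
                           mean = numeric(0), sd = numeric(0))
  }
  bad <- setdiff(evidence$gene, g)
  if (length(bad)) stop("evidence for unknown gene(s): ", paste(bad, collapse = ", "))
  if (any(evidence$time < 0 | evidence$time > n)) {
    stop("evidence time index outside 0..", n)
  }
  if (any(evidence$sd < 0)) stop("evidence SD must be >= 0")
  if (is.null(clamps)) {
    clamps <- data.frame(gene = character(0), time = integer(0),
                         mean = numeric(0), sd = numeric(0))
  }
  bad <- setdiff(clamps$gene, g)
  if (length(bad)) stop("clamp for unknown gene(s): ", paste(bad, collapse = ", "))

  mats <- dbnMatrices(dbn)
  A <- mats$W
  cvec <- mats$b
  Qd <- mats$sigma^2
  koIdx <- match(knockouts, g)
  if (length(koIdx)) {
    A[koIdx, ] <- 0
    cvec[koIdx] <- 0
    Qd[koIdx] <- 0
  }
  Q <- diag(Qd, G)
  if (is.null(init)) init <- initialSlice(dbn, knockouts)
  m <- init$mean[g]
  P <- diag(init$sd[g]^2, G)

  mf <- vector("list", n + 1L)   # filtered means
  Pf <- vector("list", n + 1L)
  mp <- vector("list", n + 1L)   # one-step predicted (mp[[t+1]] = pred of slice t from t-1)
  Pp <- vector("list", n + 1L)
  Cx <- vector("list", n + 1L)   # Cov(x_t, x_{t+1}) of the clamped dynamics
  I <- diag(1, G)

  applyClamps <- function(t, m, P) {
    cl <- clamps[clamps$time == t, , drop = FALSE]
    if (nrow(cl)) {
      idx <- match(cl$gene, g)
      m[idx] <- cl$mean
      P[idx, ] <- 0
      P[, idx] <- 0
      P[cbind(idx, idx)] <- cl$sd^2
    }
    list(m = m, P = P, idx = if (nrow(cl)) match(cl$gene, g) else integer(0))
  }
  ac <- applyClamps(0L, m, P)
  m <- ac$m
  P <- ac$P
  mp[[1]] <- m
  Pp[[1]] <- P

  for (t in 0:n) {
    ev <- evidence[evidence$time == t, , drop = FALSE]
    if (nrow(ev)) {
      idx <- match(ev$gene, g)
      H <- matrix(0, nrow(ev), G)
      H[cbind(seq_len(nrow(ev)), idx)] <- 1
      R <- diag(ev$sd^2, nrow(ev))
      S <- H %*% P %*% t(H) + R
      K <- P %*% t(H) %*% MASS::ginv(S)
      m <- m + drop(K %*% (ev$mean - drop(H %*% m)))
      IKH <- I - K %*% H
      P <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)
      P <- (P + t(P)) / 2
    }
    mf[[t + 1L]] <- m
    Pf[[t + 1L]] <- P
    if (t < n) {
      cross <- P %*% t(A)
      m <- drop(A %*% m) + cvec
      P <- A %*% P %*% t(A) + Q
      P <- (P + t(P)) / 2
      ac <- applyClamps(t + 1L, m, P)
      m <- ac$m
      P <- ac$P
      if (length(ac$idx)) cross[, ac$idx] <- 0
      mp[[t + 2L]] <- m
      Pp[[t + 2L]] <- P
      Cx[[t + 2L]] <- cross
    }
  }

  ms <- mf[[n + 1L]]
  Ps <- Pf[[n + 1L]]
  M <- matrix(NA_real_, G, n + 1L, dimnames = list(g, paste0("t", 0:n)))
  Sd <- M
  M[, n + 1L] <- ms
  Sd[, n + 1L] <- sqrt(pmax(diag(Ps), 0))
  if (n >= 1) {
    for (t in (n - 1L):0) {
      Pfil <- Pf[[t + 1L]]
      C <- Cx[[t + 2L]] %*% MASS::ginv(Pp[[t + 2L]])
      ms <- mf[[t + 1L]] + drop(C %*% (ms - mp[[t + 2L]]))
      Ps <- Pfil + C %*% (Ps - Pp[[t + 2L]]) %*% t(C)
      Ps <- (Ps + t(Ps)) / 2
      M[, t + 1L] <- ms
      Sd[, t + 1L] <- sqrt(pmax(diag(Ps), 0))
    }
  }
  if (length(koIdx)) {
    M[koIdx, ] <- 0
    Sd[koIdx, ] <- 0
  }
  new("GeneStateTrajectory", mean = M, sd = Sd, times = (0:n) * dt,
      direction = "backward")
}
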