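#' @include simulate.R smoother.R fba.R
NULL

#' Kullback-Leibler divergence between two univariate Gaussians
#'
#' \deqn{KL(N(\mu_1,\sigma_1^2) \| N(\mu_2,\sigma_2^2)) =
#'   \ln(\sigma_2/\sigma_1) + (\sigma_1^2 + (\mu_1-\mu_2)^2)/(2\sigma_2^2) - 1/2}
#'
#' @param mu1,sd1 reference (forward) Gaussian.
#' @param mu2,sd2 comparison (backward) Gaussian.
#' @return divergence in nats, >= 0. Vectorised.
#' @examples
#' gaussianKL(0, 1, 1, 1)  # 0.5
#' gaussianKL(0, 1, 0, 2)  # log(2) - 3/8
#' @export
gaussianKL <- function(mu1, sd1, mu2, sd2) {
  if (any(sd1 <= 0) || any(sd2 <= 0)) stop("SDs must be positive (floor them first)")
  log(sd2 / sd1) + (sd1^2 + (mu1 - mu2)^2) / (2 * sd2^2) - 0.5
}

#' Active experiment selection by forward/backward divergence
#'
#' Ranks genes by how much the observed growth phenotype disagrees with the
#' model's predictions about them. Forward: the coupled simulation of the
#' strain ([simulateStrain()]). Backward: the DBN smoothed on enzyme-gene
#' evidence derived from the observed growth parameters by fixed-growth FBA
#' ([boundsFromGrowth()]), applied per phase -- the pre-shift rate before the
#' observed shift time with the full medium, the post-shift rate after it
#' with glucose exhausted.
#'
#' Growth only constrains enzyme activities one-sidedly (an expressed enzyme
#' can idle without substrate), so required-activity intervals become
#' evidence in exactly two situations: a \emph{capacity deficit}, where a
#' gene's forward activity lies below the minimum activity any flux
#' distribution needs to realise the observed rate (evidence pulls it up to
#' that minimum); and a \emph{capacity excess}, where the model's own
#' predicted growth rate in a slice exceeds the observed rate, in which case
#' the genes gating the flux-carrying reactions are pulled down
#' proportionally. A self-consistent model triggers neither, so its
#' divergence is exactly zero -- the self-consistency property the selection
#' logic relies on. Rule-clamped states enter the smoother as dynamic
#' clamps. The score is
#' \eqn{D(g) = \sum_t KL(forward_{g,t} \| backward_{g,t})}, skipping
#' knocked-out genes and rule-clamped (gene, time) pairs.
#'
#' @param model a [HybridModel-class] (with any knockouts applied).
#' @param observed a [GrowthParameters-class] for the same strain context
#'   (typically the wild type).
#' @param horizon,dt simulation grid (h).
#' @param sdMin SD floor applied before each KL term.
#' @param evidenceSdMin evidence SD floor (see [boundsFromGrowth()]).
#' @param transBuffer settling time (h) after the observed shift during
#'   which no post-phase evidence is applied (the regulatory cascade needs a
#'   few slices to re-equip the cell, in the model as in the culture).
#' @param summary \code{"sum"} (default) or \code{"max"} over time.
#' @param symmetric use symmetrised KL (mean of both directions).
#' @return data.frame \code{gene}, \code{divergence}, sorted decreasing
#'   (ties: lexicographic); the per-(gene, time) divergence matrix is in
#'   attribute \code{matrix}, the backward trajectory in \code{backward}.
#' @export
adactiveRank <- function(model, observed, horizon = 45, dt = 0.5,
                         sdMin = 1e-3, evidenceSdMin = 0.05,
                         summary = c("sum", "max"), symmetric = FALSE,
                         transBuffer = 2) {
  summary <- match.arg(summary)
  fwd <- simulateStrain(model, horizon = horizon, dt = dt)
  traj <- fwd@trajectory
  n <- length(traj@times) - 1L
  met <- metabolicPart(model)
  ko <- knockouts(model)

  shiftT <- if (observed@shiftDetected && !is.na(observed@shiftTime)) {
    observed@shiftTime
  } else horizon + 1
  postBounds <- defaultBounds(met)
  exGlc <- exchangeFor(met, "glc_e")
  if (!is.na(exGlc)) postBounds$lb[postBounds$id == exGlc] <- 0

  evPre <- boundsFromGrowth(met, observed@preRate, sdMin = evidenceSdMin)
  evPost <- boundsFromGrowth(met, observed@postRate, bounds = postBounds,
                             sdMin = evidenceSdMin)
  muPred <- fwd@fluxes[biomassReaction(model), ]
  ruleGenesOf <- lapply(met@geneRules, ruleGenes)
  relTol <- 0.15
  absTol <- 0.01
  evidence <- NULL
  for (t in 0:n) {
    isPre <- traj@times[t + 1L] < shiftT
    if (!isPre && traj@times[t + 1L] < shiftT + transBuffer) next
    seg <- if (isPre) evPre$evidence else evPost$evidence
    muObs <- if (isPre) observed@preRate else observed@postRate
    if (!nrow(seg)) next
    usable <- !(seg$gene %in% ko) & !fwd@ruleApplied[seg$gene, t + 1L]
    aFwd <- clip01(traj@mean[seg$gene, t + 1L])
    # capacity deficit: forward activity below the minimum any flux
    # distribution needs to achieve the observed rate
    viol <- usable & aFwd < seg$aMin - seg$sd
    if (any(viol)) {
      evidence <- rbind(evidence,
                        data.frame(gene = seg$gene[viol], time = t,
                                   mean = seg$aMin[viol], sd = seg$sd[viol]))
    }
    # capacity excess: the model's own predicted rate in this slice exceeds
    # the observed one; pull the flux-carrying enzymes down proportionally
    mp <- muPred[max(t, 1L)]
    if (is.finite(mp) && muObs < mp * (1 - relTol) - absTol) {
      carrying <- names(ruleGenesOf)[abs(fwd@fluxes[names(ruleGenesOf), max(t, 1L)]) > 1e-6]
      gset <- setdiff(unique(unlist(ruleGenesOf[carrying])), seg$gene[viol])
      for (g2 in gset) {
        i <- match(g2, seg$gene)
        if (!is.na(i) && !usable[i]) next
        a2 <- clip01(aFwd[i] * muObs / mp)
        if (!is.na(a2) && a2 < aFwd[i] - evidenceSdMin) {
          evidence <- rbind(evidence, data.frame(gene = g2, time = t,
                                                 mean = a2, sd = evidenceSdMin))
        }
      }
    }
  }
  ra <- which(fwd@ruleApplied, arr.ind = TRUE)
  clamps <- if (nrow(ra)) {
    data.frame(gene = rownames(fwd@ruleApplied)[ra[, 1]],
               time = ra[, 2] - 1L,
               mean = traj@mean[ra], sd = traj@sd[ra])
  } else NULL
  bwd <- backwardInfer(regulatoryPart(model), evidence, n = n, knockouts = ko,
                       clamps = clamps, dt = dt)
  # the forward reference for the KL uses the same exact (full-covariance)
  # prior the smoother propagates, so that with no evidence the two sides
  # are identical by construction (the means coincide with the mean-field
  # simulation; only the SDs of correlated-parent children differ)
  fref <- backwardInfer(regulatoryPart(model), NULL, n = n, knockouts = ko,
                        clamps = clamps, dt = dt)

  s1 <- pmax(fref@sd, sdMin)
  s2 <- pmax(bwd@sd, sdMin)
  D <- gaussianKL(fref@mean, s1, bwd@mean, s2)
  if (symmetric) D <- (D + gaussianKL(bwd@mean, s2, traj@mean, s1)) / 2
  D[fwd@ruleApplied] <- 0
  if (length(ko)) D[ko, ] <- 0
  score <- if (summary == "sum") rowSums(D) else apply(D, 1, max)
  genesOut <- setdiff(rownames(D), ko)
  out <- data.frame(gene = genesOut, divergence = unname(score[genesOut]))
  out <- out[order(-out$divergence, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "matrix") <- D
  attr(out, "backward") <- bwd
  attr(out, "evidence") <- evidence
  out
}

#' Regulator influence profiles from expression data
#'
#' The influence of a regulator at time t is the standardised mean expression
#' of its activated targets minus that of its repressed targets; the profile
#' is binarised at 0 and classified by the majority label before vs after the
#' shift index (dataset midpoint unless supplied): \code{"active->inactive"},
#' \code{"inactive->active"} or \code{"stable"}.
#'
#' @param data expression matrix, genes x time points.
#' @param targets named list per regulator: \code{list(activated =, repressed =)}.
#' @param shiftIndex column index separating the two phases (default
#'   midpoint).
#' @return data.frame \code{regulator}, \code{class}; the influence matrix
#'   (regulators x time) is in attribute \code{influence}.
#' @export
influenceProfiles <- function(data, targets, shiftIndex = NULL) {
  stopifnot(length(targets) >= 1)
  if (is.null(shiftIndex)) shiftIndex <- floor(ncol(data) / 2)
  z <- t(scale(t(data)))
  z[!is.finite(z)] <- 0
  infl <- matrix(0, length(targets), ncol(data),
                 dimnames = list(names(targets), colnames(data)))
  for (r in names(targets)) {
    act <- intersect(targets[[r]]$activated, rownames(data))
    rep_ <- intersect(targets[[r]]$repressed, rownames(data))
    if (!length(act) && !length(rep_)) {
      warning("regulator '", r, "' has no expressed targets; profile is zero")
      next
    }
    a <- if (length(act)) colMeans(z[act, , drop = FALSE]) else 0
    b <- if (length(rep_)) colMeans(z[rep_, , drop = FALSE]) else 0
    infl[r, ] <- a - b
  }
  lab <- infl > 0
  classify <- function(i) {
    before <- mean(lab[i, seq_len(shiftIndex)]) > 0.5
    after <- mean(lab[i, (shiftIndex + 1L):ncol(lab)]) > 0.5
    if (before && !after) "active->inactive"
    else if (!before && after) "inactive->active"
    else "stable"
  }
  out <- data.frame(regulator = rownames(infl),
                    class = vapply(seq_len(nrow(infl)), classify, ""),
                    stringsAsFactors = FALSE)
  attr(out, "influence") <- infl
  out
}

#' Candidate regulators from antagonistic coregulation subgraphs
#'
#' Builds the coregulation graph (edge between regulators whose target sets
#' have Jaccard similarity >= \code{jMin}), extracts class-uniform dense
#' subgraphs by greedy peeling (repeatedly dropping the minimum-degree node
#' until edge density >= \code{dMin}), and, for every antagonistic subgraph
#' pair joined by at least one edge, returns the regulators on the
#' active->inactive side that are adjacent to the other side (the border
#' regulators), de-duplicated and ordered by their cross-edge count.
#'
#' @param profiles output of [influenceProfiles()].
#' @param targets the same target list used for the profiles.
#' @param jMin Jaccard threshold (default 0.3).
#' @param dMin density threshold for a dense subgraph (default 0.6).
#' @return character vector of candidate regulators (possibly empty).
#' @export
coregmineSelect <- function(profiles, targets, jMin = 0.3, dMin = 0.6) {
  regs <- profiles$regulator
  if (length(regs) < 2) stop("need at least 2 regulators")
  tsets <- lapply(targets[regs], function(t) unique(c(t$activated, t$repressed)))
  n <- length(regs)
  adj <- matrix(FALSE, n, n, dimnames = list(regs, regs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- length(union(tsets[[i]], tsets[[j]]))
      jac <- if (u == 0) 0 else length(intersect(tsets[[i]], tsets[[j]])) / u
      adj[i, j] <- adj[j, i] <- jac >= jMin
    }
  }
  cls <- setNames(profiles$class, regs)
  denseGroups <- list()
  for (cl in unique(cls)) {
    members <- regs[cls == cl]
    # connected components within the class
    remaining <- members
    while (length(remaining)) {
      comp <- remaining[1]
      repeat {
        nb <- regs[colSums(adj[comp, , drop = FALSE]) > 0]
        grow <- intersect(setdiff(nb, comp), remaining)
        if (!length(grow)) break
        comp <- c(comp, grow)
      }
      remaining <- setdiff(remaining, comp)
      # greedy peel to density
      while (length(comp) > 1) {
        E <- sum(adj[comp, comp]) / 2
        dens <- E / (length(comp) * (length(comp) - 1) / 2)
        if (dens >= dMin) break
        deg <- rowSums(adj[comp, comp, drop = FALSE])
        comp <- comp[-which.min(deg)]
      }
      if (length(comp)) {
        denseGroups[[length(denseGroups) + 1L]] <- list(nodes = sort(comp), class = cl)
      }
    }
  }
  isA <- vapply(denseGroups, function(gr) gr$class == "active->inactive", TRUE)
  isB <- vapply(denseGroups, function(gr) gr$class == "inactive->active", TRUE)
  border <- character(0)
  crossCount <- numeric(0)
  for (ga in denseGroups[isA]) {
    for (gb in denseGroups[isB]) {
      cross <- adj[ga$nodes, gb$nodes, drop = FALSE]
      if (!any(cross)) next
      sel <- ga$nodes[rowSums(cross) > 0]
      for (s in sel) {
        cc <- sum(cross[s, ])
        if (s %in% border) {
          crossCount[match(s, border)] <- crossCount[match(s, border)] + cc
        } else {
          border <- c(border, s)
          crossCount <- c(crossCount, cc)
        }
      }
    }
  }
  border[order(-crossCount, border)]
}

#' Discriminative strain selection between two models
#'
#' Ranks candidate deletant strains by the absolute disagreement of the two
#' models' predicted post-shift growth rates, and keeps the top k -- the
#' "crucial" experiments that best tell the models apart.
#'
#' @param modelA,modelB [HybridModel-class] rivals.
#' @param candidates knockable gene ids present in both models.
#' @param k number of strains to select.
#' @param horizon,dt simulation grid (h).
#' @return data.frame \code{gene}, \code{disagreement}, top k rows, sorted
#'   decreasing (ties: lexicographic).
#' @export
adanaDisagreement <- function(modelA, modelB, candidates, k,
                              horizon = 45, dt = 0.5) {
  stopifnot(all(candidates %in% genes(modelA)), all(candidates %in% genes(modelB)))
  d <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (g in candidates) {
    d[g] <- tryCatch({
      pa <- growthParams(simulateStrain(applyKnockout(modelA, g),
                                        horizon = horizon, dt = dt))@postRate
      pb <- growthParams(simulateStrain(applyKnockout(modelB, g),
                                        horizon = horizon, dt = dt))@postRate
      abs(pa - pb)
    }, error = function(e) {
      warning("skipping strain ", g, ": ", conditionMessage(e))
      NA_real_
    })
  }
  out <- data.frame(gene = candidates, disagreement = unname(d))
  out <- out[!is.na(out$disagreement), , drop = FALSE]
  out <- out[order(-out$disagreement, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  head(out, k)
}

#' Gene importance in a hybrid model
#'
#' importance(g) = |post-shift rate(wild type) - post-shift rate(delta g)| +
#' lambdaC * sum of absolute outgoing edge weights above the display
#' threshold (0.3).
#'
#' @param model a [HybridModel-class].
#' @param geneIds genes to score (default: all knockable genes).
#' @param lambdaC weight of the connectivity term (default 0.1).
#' @param wThresh edge-strength display threshold (default 0.3).
#' @param horizon,dt simulation grid (h).
#' @return data.frame \code{gene}, \code{importance}, sorted decreasing.
#' @export
adanaImportance <- function(model, geneIds = genes(model), lambdaC = 0.1,
                            wThresh = 0.3, horizon = 45, dt = 0.5) {
  wt <- growthParams(simulateStrain(model, horizon = horizon, dt = dt))@postRate
  e <- dbnEdges(model)
  imp <- vapply(geneIds, function(g) {
    dg <- growthParams(simulateStrain(applyKnockout(model, g),
                                      horizon = horizon, dt = dt))@postRate
    w <- abs(e$weight[e$parent == g])
    abs(wt - dg) + lambdaC * sum(w[w > wThresh])
  }, 0)
  out <- data.frame(gene = geneIds, importance = unname(imp))
  out <- out[order(-out$importance, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random experiment selection
#'
#' Uniform sample of k candidate strains without replacement, seeded.
#'
#' @param candidates candidate gene ids.
#' @param k sample size (k <= length(candidates)).
#' @param seed RNG seed.
#' @return character vector of k gene ids.
#' @export
randomDesign <- function(candidates, k, seed = 1) {
  if (k > length(candidates)) stop("k exceeds the candidate pool")
  withSeed(seed, base::sample(candidates, k))
}

#' Write an experiment-request table
#'
#' The artifact's stand-in for robot experiment requests: one row per
#' requested deletant strain.
#'
#' @param strains character vector of strain genes, in rank order.
#' @param method design method name (\code{adactive}, \code{coregmine},
#'   \code{adana}, \code{random}).
#' @param scores optional numeric scores aligned with \code{strains}.
#' @param path CSV path.
#' @export
writeExperimentRequests <- function(strains, method, scores = NA_real_, path) {
  df <- data.frame(strain_gene = strains, method = method, score = scores,
                   rank = seq_along(strains))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
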