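#' @include simulate.R phenotype.R
NULL

#' Observe strains in the virtual laboratory
#'
#' Runs one virtual growth experiment per strain, preprocesses the replicate
#' curves and extracts growth parameters -- producing the observation table
#' consumed by [postshiftError()] and [refineModel()].
#'
#' @param truth ground-truth [HybridModel-class].
#' @param strains character vector of strain labels: a gene id, genes joined
#'   by \code{"+"}, or \code{"WT"} for the wild type.
#' @param config a [labConfig()]; per-strain noise seeds derive from
#'   \code{config$seed}.
#' @return data.frame \code{strain}, \code{postRate}, \code{preRate},
#'   \code{shiftTime}, \code{shiftDetected}, \code{replicates}, \code{source}.
#' @export
observeStrains <- function(truth, strains, config = labConfig()) {
  out <- NULL
  for (i in seq_along(strains)) {
    cfg <- config
    cfg$seed <- subSeed(config$seed, 1000L + i)
    raw <- runVirtualExperiment(truth, strainGenes(strains[i]), cfg)
    curve <- suppressWarnings(preprocessCurve(raw, minReps = cfg$replicates))
    gp <- growthParameters(curve)
    out <- rbind(out, data.frame(
      strain = strains[i], postRate = gp@postRate, preRate = gp@preRate,
      shiftTime = gp@shiftTime, shiftDetected = gp@shiftDetected,
      replicates = cfg$replicates, source = "virtual_lab",
      stringsAsFactors = FALSE))
  }
  out
}

strainGenes <- function(label) {
  if (is.na(label) || label %in% c("", "WT")) return(character(0))
  strsplit(label, "+", fixed = TRUE)[[1]]
}

#' Post-shift growth-rate prediction error
#'
#' For every observed strain, simulates the model with that strain's
#' deletion(s) and reports the absolute difference between predicted and
#' observed post-shift growth rate -- the error currency of model revision
#' and evaluation. Strains whose simulation fails are excluded with a
#' warning.
#'
#' @param model the [HybridModel-class] under evaluation.
#' @param observations observation table (see [observeStrains()]); needs
#'   columns \code{strain} and \code{postRate}.
#' @param horizon,dt simulation grid (h).
#' @return list: \code{errors} (named per-strain vector, 1/h), \code{mae}
#'   (mean absolute error), \code{n}.
#' @export
postshiftError <- function(model, observations, horizon = 45, dt = 0.5) {
  stopifnot(nrow(observations) >= 1)
  errs <- setNames(rep(NA_real_, nrow(observations)), observations$strain)
  for (i in seq_len(nrow(observations))) {
    errs[i] <- tryCatch({
      gp <- growthParams(simulateStrain(
        applyKnockout(model, strainGenes(observations$strain[i])),
        horizon = horizon, dt = dt))
      abs(gp@postRate - observations$postRate[i])
    }, error = function(e) {
      warning("excluding strain ", observations$strain[i], ": ",
              conditionMessage(e))
      NA_real_
    })
  }
  errs <- errs[!is.na(errs)]
  list(errors = errs, mae = mean(errs), n = length(errs))
}

#' Score candidate edge removals without simulation
#'
#' The cheap prior-scoring step of model revision: full simulation of every
#' candidate change is too costly, so edges are ranked first by a structural
#' heuristic. Over the worst-predicted strains (the top error quartile by
#' count, among errors above \code{tol}), an edge scores |w| whenever it can
#' plausibly carry the
#' mis-prediction: it lies on a directed path out of the strain's deleted
#' gene(s), or on a directed path into a rule-clamped gene. Perfectly
#' predicted observations propose no candidates.
#'
#' @inheritParams postshiftError
#' @param errors optional precomputed result of [postshiftError()].
#' @param tol errors at or below this are treated as perfect predictions.
#' @return data.frame \code{parent}, \code{child}, \code{weight},
#'   \code{score}, sorted by score (ties: lexicographic); zero-score edges
#'   are kept at the bottom.
#' @export
scoreCandidateRemovals <- function(model, observations, errors = NULL,
                                   horizon = 45, dt = 0.5, tol = 1e-6) {
  e <- dbnEdges(model)
  # autoregressive self-edges encode degradation kinetics, not regulatory
  # hypotheses; they are not candidates for removal
  e <- e[e$parent != e$child, , drop = FALSE]
  if (!nrow(e)) stop("model has no removable regulatory edge")
  if (is.null(errors)) errors <- postshiftError(model, observations, horizon, dt)
  errVec <- errors$errors
  pos <- errVec[errVec > tol]
  # top error quartile by count (deterministic under ties)
  worst <- if (length(pos)) {
    ord <- order(-pos, names(pos))
    names(pos)[ord][seq_len(ceiling(length(errVec) / 4))]
  } else character(0)
  worst <- worst[!is.na(worst)]
  ruleTargets <- unique(metaboliteRules(model)$target)
  intoRule <- if (length(ruleTargets)) {
    upstream <- reachingTo(e[c("parent", "child")], ruleTargets)
    e$child %in% upstream | e$child %in% ruleTargets
  } else rep(FALSE, nrow(e))
  score <- rep(0, nrow(e))
  for (s in worst) {
    del <- strainGenes(s)
    fromDel <- if (length(del)) {
      down <- reachableFrom(e[c("parent", "child")], del)
      e$parent %in% down
    } else rep(FALSE, nrow(e))
    score <- score + abs(e$weight) * as.numeric(fromDel | intoRule)
  }
  out <- data.frame(parent = e$parent, child = e$child, weight = e$weight,
                    score = score)
  out <- out[order(-out$score, out$parent, out$child), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy validated model revision by edge removal
#'
#' Iterates the ranked removal candidates: each edge is tentatively removed,
#' the post-shift error against the observations recomputed, and the removal
#' accepted only if the mean absolute error drops by at least
#' \code{minGain}; after every acceptance the candidates are re-ranked.
#' Rejected removals are not retried (greedy with a tabu list). Stops when
#' \code{maxEvals} error evaluations have been spent or no remaining
#' candidate improves. Only removals are enacted. Acceptance is
#' purely error-driven, and the accepted-step error sequence is strictly
#' decreasing by construction.
#'
#' @inheritParams postshiftError
#' @param maxEvals budget of tentative-removal error evaluations (>= 1).
#' @param minGain minimum absolute MAE improvement to accept (1/h).
#' @return list: \code{model} (revised), \code{trace} (data.frame
#'   \code{parent}, \code{child}, \code{action}, \code{errorBefore},
#'   \code{errorAfter}), \code{errorBefore}, \code{errorAfter},
#'   \code{evals}.
#' @export
refineModel <- function(model, observations, maxEvals = 8, minGain = 1e-4,
                        horizon = 45, dt = 0.5, tol = 1e-6) {
  stopifnot(maxEvals >= 1)
  err <- postshiftError(model, observations, horizon, dt)
  err0 <- err$mae
  evals <- 0L
  trace <- data.frame(parent = character(0), child = character(0),
                      action = character(0), errorBefore = numeric(0),
                      errorAfter = numeric(0), stringsAsFactors = FALSE)
  tabu <- character(0)   # rejected removals are not retried
  repeat {
    cand <- scoreCandidateRemovals(model, observations, errors = err,
                                   horizon = horizon, dt = dt, tol = tol)
    cand <- cand[cand$score > 0 & !(paste(cand$parent, cand$child) %in% tabu),
                 , drop = FALSE]
    improved <- FALSE
    for (i in seq_len(nrow(cand))) {
      if (evals >= maxEvals) break
      test <- model
      dbn <- test@regulatory
      drop_ <- dbn@edges$parent == cand$parent[i] & dbn@edges$child == cand$child[i]
      dbn@edges <- dbn@edges[!drop_, , drop = FALSE]
      test@regulatory <- dbn
      e2 <- postshiftError(test, observations, horizon, dt)
      evals <- evals + 1L
      if (e2$mae <= err$mae - minGain) {
        trace <- rbind(trace, data.frame(
          parent = cand$parent[i], child = cand$child[i], action = "accepted",
          errorBefore = err$mae, errorAfter = e2$mae))
        model <- test
        err <- e2
        improved <- TRUE
        break
      } else {
        trace <- rbind(trace, data.frame(
          parent = cand$parent[i], child = cand$child[i], action = "rejected",
          errorBefore = err$mae, errorAfter = e2$mae))
        tabu <- c(tabu, paste(cand$parent[i], cand$child[i]))
      }
    }
    if (!improved || evals >= maxEvals) break
  }
  list(model = model, trace = trace, errorBefore = err0, errorAfter = err$mae,
       evals = evals)
}

#' Export a revision trace
#'
#' @param trace the \code{trace} component of [refineModel()]'s result.
#' @param path TSV path.
#' @export
writeRevisionTrace <- function(trace, path) {
  write.table(trace, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
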