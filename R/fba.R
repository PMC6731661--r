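#' @include model-core.R lp.R
NULL

#' Default reaction bounds of a metabolic model
#'
#' @param model a [MetabolicModel-class].
#' @return data.frame \code{id}, \code{lb}, \code{ub}.
#' @export
defaultBounds <- function(model) {
  model@reactions[c("id", "lb", "ub")]
}

#' Scale reaction bounds by enzyme gene states
#'
#' For every reaction carrying a gene-reaction rule, the rule is evaluated on
#' the slice's gene means clipped to [0, 1] (AND = min, OR = max, knocked-out
#' genes = 0) and both default bounds are scaled linearly by the resulting
#' activity; reactions without a rule keep their defaults. Linear scaling of
#' bounds by mean activity is the minimal monotone gene-to-flux coupling and
#' is deliberately isolated here so it can be swapped out.
#'
#' @param model a [MetabolicModel-class].
#' @param slice gene-state slice covering every gene referenced by a rule.
#' @param knockouts deleted genes (their rule literals evaluate to 0).
#' @return bounds data.frame \code{id}, \code{lb}, \code{ub}.
#' @export
geneStatesToBounds <- function(model, slice, knockouts = character(0)) {
  bounds <- defaultBounds(model)
  if (!length(model@geneRules)) return(bounds)
  act <- slice$mean
  for (rid in names(model@geneRules)) {
    a <- evalGeneRule(model@geneRules[[rid]], act, knockouts)
    j <- match(rid, bounds$id)
    bounds$lb[j] <- bounds$lb[j] * a
    bounds$ub[j] <- bounds$ub[j] * a
  }
  bounds
}

# Precompiled numeric view of a metabolic model, shared by the public FBA
# functions and the simulation hot loop (built once, used per step).
metContext <- function(model) {
  rid <- model@reactions$id
  met <- model@metabolites
  kin <- model@uptakeKinetics
  kinRows <- lapply(seq_len(nrow(kin)), function(i) {
    list(metId = kin$metabolite[i],
         exIdx = match(kin$exchange[i], rid),
         vmax = kin$vmax[i], km = kin$km[i],
         buffered = met$buffered[match(kin$metabolite[i], met$id)])
  })
  tracked <- met$id[met$external & !met$buffered]
  trackedEx <- vapply(tracked, function(m) {
    ex <- exchangeFor(model, m)
    if (is.na(ex)) NA_integer_ else match(ex, rid)
  }, 0L)
  rules <- lapply(model@geneRules, identity)
  ruleIdx <- match(names(rules), rid)
  list(S = model@stoich, rid = rid,
       lb0 = model@reactions$lb, ub0 = model@reactions$ub,
       bioIdx = match(model@biomassId, rid),
       rules = rules, ruleIdx = ruleIdx,
       kin = kinRows, tracked = tracked, trackedEx = trackedEx,
       zeroRHS = rep(0, nrow(model@stoich)),
       Apn = cbind(model@stoich, -model@stoich))
}

# core LP: max (or min) flux of reaction objIdx subject to S v = 0 and bounds
fbaCore <- function(ctx, lb, ub, objIdx, maximize = TRUE) {
  obj <- numeric(length(ctx$rid))
  obj[objIdx] <- 1
  solveLP(obj, ctx$S, ctx$zeroRHS, lb, ub, maximize = maximize)
}

# parsimonious flux distribution at a fixed flux value (split-variable LP)
pfbaCore <- function(ctx, lb, ub, fixIdx, fixVal) {
  eps <- 1e-9
  lb[fixIdx] <- max(lb[fixIdx], fixVal - eps)
  ub[fixIdx] <- min(ub[fixIdx], fixVal + eps)
  nR <- length(ctx$rid)
  lbs <- c(pmax(0, lb), pmax(0, -ub))
  ubs <- c(pmax(0, ub), pmax(0, -lb))
  sol <- solveLP(rep(1, 2 * nR), ctx$Apn, ctx$zeroRHS, lbs, ubs, maximize = FALSE)
  if (sol$status != "optimal") return(NULL)
  sol$x[seq_len(nR)] - sol$x[nR + seq_len(nR)]
}

#' Flux balance analysis
#'
#' Solves the flux LP: optimise the objective reaction's flux subject to
#' steady state (S v = 0) and the given bounds. With \code{pfba = TRUE} a
#' second LP minimises total absolute flux at the optimal objective value
#' (parsimonious FBA), which resolves degenerate optima deterministically.
#'
#' @param model a [MetabolicModel-class].
#' @param bounds bounds data.frame (default [defaultBounds()]).
#' @param objective objective reaction id (default the biomass reaction).
#' @param sense \code{"max"} or \code{"min"}.
#' @param pfba apply the parsimonious tie-break.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{fluxes} (named vector, absent unless
#'   optimal), and \code{objective} (the optimal objective flux).
#' @examples
#' \dontrun{
#' sol <- solveFBA(metabolicPart(model))
#' sol$objective  # mu in 1/h
#' }
#' @export
solveFBA <- function(model, bounds = NULL, objective = NULL, sense = "max",
                     pfba = FALSE) {
  if (is.null(bounds)) bounds <- defaultBounds(model)
  if (is.null(objective)) objective <- model@biomassId
  rid <- model@reactions$id
  stopifnot(objective %in% rid)
  if (any(bounds$lb > bounds$ub)) {
    stop("inconsistent bounds (lb > ub) for: ",
         paste(bounds$id[bounds$lb > bounds$ub], collapse = ", "))
  }
  lb <- bounds$lb[match(rid, bounds$id)]
  ub <- bounds$ub[match(rid, bounds$id)]
  ctx <- metContext(model)
  sol <- fbaCore(ctx, lb, ub, match(objective, rid), maximize = (sense == "max"))
  if (sol$status != "optimal") {
    return(list(status = sol$status, objective = NA_real_))
  }
  v <- setNames(sol$x, rid)
  objVal <- unname(v[objective])
  if (pfba) {
    vp <- pfbaCore(ctx, lb, ub, match(objective, rid), objVal)
    if (!is.null(vp)) v <- setNames(vp, rid)
  }
  list(status = "optimal", fluxes = v, objective = objVal)
}

#' Flux variability at a fixed objective value
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' steady state, the bounds, and any fixed fluxes.
#'
#' @inheritParams solveFBA
#' @param reactions reaction ids to scan.
#' @param fix named numeric of fluxes to pin (e.g. the biomass flux).
#' @return data.frame \code{id}, \code{min}, \code{max}.
#' @export
fluxVariability <- function(model, reactions, bounds = NULL, fix = numeric(0)) {
  if (is.null(bounds)) bounds <- defaultBounds(model)
  rid <- model@reactions$id
  lb <- bounds$lb[match(rid, bounds$id)]
  ub <- bounds$ub[match(rid, bounds$id)]
  eps <- 1e-9
  for (r in names(fix)) {
    j <- match(r, rid)
    lb[j] <- max(lb[j], fix[[r]] - eps)
    ub[j] <- min(ub[j], fix[[r]] + eps)
  }
  S <- model@stoich
  out <- data.frame(id = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    obj <- as.numeric(rid == reactions[k])
    lo <- solveLP(obj, S, rep(0, nrow(S)), lb, ub, maximize = FALSE)
    hi <- solveLP(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
    if (lo$status == "optimal") out$min[k] <- lo$value
    if (hi$status == "optimal") out$max[k] <- hi$value
  }
  out
}

#' Export a flux/bounds table
#'
#' Writes one row per reaction: id, the bounds used, and (when supplied) the
#' solved flux.
#'
#' @param bounds bounds data.frame (\code{id}, \code{lb}, \code{ub}).
#' @param path TSV path.
#' @param fluxes optional named flux vector from [solveFBA()].
#' @export
writeFluxTSV <- function(bounds, path, fluxes = NULL) {
  out <- bounds
  if (!is.null(fluxes)) out$flux <- unname(fluxes[out$id])
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enzyme-gene evidence from an observed growth rate
#'
#' The inverse (fixed-growth) mode: instead of maximising growth, the biomass
#' flux is pinned to the observed rate and the flux space consistent with it
#' is characterised. A parsimonious flux distribution is computed, then the
#' flux-variability range of every rule-bearing reaction at the fixed growth;
#' each range is translated into a required activity interval (|flux| as a
#' fraction of the default bound magnitude) and summarised per enzyme gene as
#' a Gaussian: mean = interval midpoint, SD = width/4 floored at
#' \code{sdMin}. A gene appearing in several rules takes the narrowest
#' (most informative) interval. If the observed rate is infeasible the
#' maximum achievable rate is used instead and flagged with a warning.
#'
#' @param model a [MetabolicModel-class].
#' @param observedMu observed specific growth rate (1/h), >= 0.
#' @param bounds optional bounds data.frame overriding defaults (e.g. with
#'   exchange caps reflecting the medium at the observed phase).
#' @param sdMin evidence SD floor (default 0.05).
#' @return list with \code{evidence}: data.frame \code{gene}, \code{mean},
#'   \code{sd}; \code{ranges}: per-reaction activity intervals; \code{mu}:
#'   the growth rate actually used; \code{feasible} flag.
#' @export
boundsFromGrowth <- function(model, observedMu, bounds = NULL, sdMin = 0.05) {
  stopifnot(observedMu >= 0)
  if (is.null(bounds)) bounds <- defaultBounds(model)
  maxSol <- solveFBA(model, bounds)
  muMax <- if (maxSol$status == "optimal") maxSol$objective else 0
  feasible <- observedMu <= muMax + 1e-9
  mu <- if (feasible) observedMu else {
    warning(sprintf("observed growth rate %.4g exceeds the maximum achievable %.4g; using the maximum",
                    observedMu, muMax))
    muMax
  }
  ruleRxns <- names(model@geneRules)
  fix <- setNames(mu, model@biomassId)
  fv <- fluxVariability(model, ruleRxns, bounds = bounds, fix = fix)
  dflt <- defaultBounds(model)
  mag <- pmax(abs(dflt$lb), abs(dflt$ub))[match(ruleRxns, dflt$id)]
  aMin <- clip01(pmin(abs(fv$min), abs(fv$max)) / pmax(mag, 1e-12))
  aMax <- clip01(pmax(abs(fv$min), abs(fv$max)) / pmax(mag, 1e-12))
  spans0 <- sign(fv$min) != sign(fv$max)  # zero flux admissible
  aMin[spans0] <- 0
  ranges <- data.frame(id = ruleRxns, aMin = aMin, aMax = aMax,
                       stringsAsFactors = FALSE)
  ev <- list()
  for (k in seq_along(ruleRxns)) {
    for (g in ruleGenes(model@geneRules[[ruleRxns[k]]])) {
      width <- aMax[k] - aMin[k]
      cur <- ev[[g]]
      if (is.null(cur) || width < cur$width) {
        ev[[g]] <- list(mean = (aMin[k] + aMax[k]) / 2, width = width)
      }
    }
  }
  evidence <- data.frame(
    gene = names(ev),
    mean = vapply(ev, function(e) e$mean, 0),
    sd = vapply(ev, function(e) max(e$width / 4, sdMin), 0),
    aMin = vapply(ev, function(e) e$mean - e$width / 2, 0),
    aMax = vapply(ev, function(e) e$mean + e$width / 2, 0),
    stringsAsFactors = FALSE)
  rownames(evidence) <- NULL
  list(evidence = evidence, ranges = ranges, mu = mu, feasible = feasible)
}
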