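#' @include diauxloop-package.R
NULL

#' Two-slice linear-Gaussian dynamic Bayesian network
#'
#' The signalling layer of a hybrid model. Every node is a gene/protein tagged
#' either \code{"regulator"} (may have children) or \code{"enzyme"} (leaf
#' nodes wired to metabolic reactions through gene-reaction rules). The
#' conditional of node \eqn{g} given slice \eqn{t} is
#' \deqn{X_{g,t+1} \mid X_{\cdot,t} \sim
#'   N\!\left(b_g + \textstyle\sum_{p \in pa(g)} w_{pg} X_{p,t},\; \sigma_g^2\right)}
#' with a fixed one-slice lag on every edge. Gene activities are nominally in
#' \eqn{[0,1]} (0 = inactive, 1 = fully active) but are propagated as
#' unbounded Gaussians; clipping happens only where activities gate reaction
#' bounds.
#'
#' @slot nodes character vector of gene ids.
#' @slot nodeType named character, \code{"regulator"} or \code{"enzyme"} per node.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{weight}; parents must be regulators.
#' @slot bias,sigma named numerics: intercept and noise SD per node.
#' @slot initMean,initSd named numerics: the slice-0 state distribution.
#'
#' @seealso [regulatoryDBN()] for the user-facing constructor.
#' @export
setClass("RegulatoryDBN",
  representation(
    nodes = "character",
    nodeType = "character",
    edges = "data.frame",
    bias = "numeric",
    sigma = "numeric",
    initMean = "numeric",
    initSd = "numeric"
  )
)

setValidity("RegulatoryDBN", function(object) {
  msg <- character(0)
  n <- object@nodes
  if (anyDuplicated(n)) msg <- c(msg, "duplicate node ids")
  for (sl in c("nodeType", "bias", "sigma", "initMean", "initSd")) {
    v <- slot(object, sl)
    if (!identical(sort(names(v)), sort(n))) {
      msg <- c(msg, sprintf("slot '%s' must be named by exactly the node set", sl))
    }
  }
  if (!all(object@nodeType %in% c("regulator", "enzyme"))) {
    msg <- c(msg, "nodeType values must be 'regulator' or 'enzyme'")
  }
  e <- object@edges
  if (!all(c("parent", "child", "weight") %in% names(e))) {
    msg <- c(msg, "edges needs columns parent, child, weight")
  } else if (nrow(e)) {
    if (!all(e$parent %in% n) || !all(e$child %in% n)) {
      msg <- c(msg, "edge endpoints must exist in nodes")
    }
    bad <- setdiff(unique(e$parent), n[object@nodeType[n] == "regulator"])
    bad <- intersect(bad, n)
    if (length(bad)) {
      msg <- c(msg, sprintf("enzyme cannot have children: %s",
                            paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(e[c("parent", "child")])) {
      msg <- c(msg, "duplicate (parent, child) pairs")
    }
  }
  if (length(object@sigma) && any(object@sigma < 0)) msg <- c(msg, "negative noise SD")
  if (length(object@initSd) && any(object@initSd < 0)) msg <- c(msg, "negative initial SD")
  if (length(msg)) msg else TRUE
})

#' Stoichiometric metabolic model
#'
#' A flux-balance model: stoichiometric matrix \eqn{S} (metabolites x
#' reactions), default flux bounds in mmol/gDW/h, a designated biomass
#' reaction whose flux is the specific growth rate \eqn{\mu} (1/h), exchange
#' reactions connecting medium metabolites to the network, boolean
#' gene-reaction rules over enzyme genes, and Michaelis-Menten uptake
#' kinetics used by the dynamic stepping.
#'
#' Medium metabolites (\code{external = TRUE}) have their concentrations (mM)
#' tracked by [dfbaStep()]; \code{buffered} metabolites (e.g. oxygen under
#' aeration, outgassing CO2) are held at a constant concentration.
#' \code{carbon} holds atoms per molecule for conservation checks.
#'
#' @slot stoich numeric matrix, metabolites x reactions.
#' @slot metabolites data.frame: \code{id}, \code{external}, \code{buffered},
#'   \code{carbon}.
#' @slot reactions data.frame: \code{id}, \code{lb}, \code{ub},
#'   \code{reversible}.
#' @slot biomassId id of the biomass (growth) reaction.
#' @slot exchangeIds ids of exchange reactions.
#' @slot geneRules named list of parsed boolean rules (see [parseGeneRule()]).
#' @slot uptakeKinetics data.frame: \code{metabolite}, \code{exchange},
#'   \code{vmax}, \code{km}.
#' @export
setClass("MetabolicModel",
  representation(
    stoich = "matrix",
    metabolites = "data.frame",
    reactions = "data.frame",
    biomassId = "character",
    exchangeIds = "character",
    geneRules = "list",
    uptakeKinetics = "data.frame"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  S <- object@stoich
  met <- object@metabolites
  rxn <- object@reactions
  if (!identical(rownames(S), met$id)) msg <- c(msg, "stoich rows must match metabolite ids")
  if (!identical(colnames(S), rxn$id)) msg <- c(msg, "stoich columns must match reaction ids")
  if (nrow(rxn) && any(rxn$lb > rxn$ub)) {
    msg <- c(msg, sprintf("lower bound exceeds upper bound for: %s",
                          paste(rxn$id[rxn$lb > rxn$ub], collapse = ", ")))
  }
  if (length(object@biomassId) != 1L || !(object@biomassId %in% rxn$id)) {
    msg <- c(msg, "biomass reaction missing from reactions")
  }
  if (!all(object@exchangeIds %in% rxn$id)) msg <- c(msg, "unknown exchange reaction id")
  if (length(object@geneRules)) {
    if (!all(names(object@geneRules) %in% rxn$id)) {
      msg <- c(msg, "gene rule attached to unknown reaction")
    }
  }
  uk <- object@uptakeKinetics
  if (nrow(uk)) {
    if (!all(uk$metabolite %in% met$id)) msg <- c(msg, "kinetics for unknown metabolite")
    if (!all(uk$exchange %in% object@exchangeIds)) msg <- c(msg, "kinetics for unknown exchange")
  }
  if (length(msg)) msg else TRUE
})

#' Hybrid regulatory-metabolic model
#'
#' Couples a [RegulatoryDBN-class] to a [MetabolicModel-class] through (a)
#' gene-reaction rules evaluated on enzyme gene states to scale reaction
#' bounds, and (b) metabolite-to-gene rules that overwrite regulator states
#' when a medium concentration crosses a threshold (the diauxic-shift
#' "regularization" step). Deleted genes are listed in \code{knockouts}: a
#' knocked-out gene is clamped to state (0, 0) at every slice and its
#' gene-reaction rule literal evaluates to 0.
#'
#' @slot regulatory the signalling DBN.
#' @slot metabolic the stoichiometric model.
#' @slot rules data.frame of metabolite rules: \code{metabolite},
#'   \code{comparator} (\code{"lt"} or \code{"ge"}), \code{threshold} (mM),
#'   \code{target}, \code{mean}, \code{sd}.
#' @slot knockouts character vector of deleted gene ids.
#' @export
setClass("HybridModel",
  representation(
    regulatory = "RegulatoryDBN",
    metabolic = "MetabolicModel",
    rules = "data.frame",
    knockouts = "character"
  )
)

setValidity("HybridModel", function(object) {
  msg <- character(0)
  dbn <- object@regulatory
  met <- object@metabolic
  nodes <- dbn@nodes
  enz <- nodes[dbn@nodeType[nodes] == "enzyme"]
  for (rid in names(met@geneRules)) {
    gs <- ruleGenes(met@geneRules[[rid]])
    missing <- setdiff(gs, enz)
    if (length(missing)) {
      msg <- c(msg, sprintf("gene rule of '%s' references non-enzyme gene(s): %s",
                            rid, paste(missing, collapse = ", ")))
    }
  }
  r <- object@rules
  if (nrow(r)) {
    need <- c("metabolite", "comparator", "threshold", "target", "mean", "sd")
    if (!all(need %in% names(r))) {
      msg <- c(msg, "rules needs columns metabolite, comparator, threshold, target, mean, sd")
    } else {
      if (!all(r$comparator %in% c("lt", "ge"))) msg <- c(msg, "rule comparator must be 'lt' or 'ge'")
      if (any(r$threshold < 0)) msg <- c(msg, "rule threshold must be >= 0")
      bad <- setdiff(r$target, nodes)
      if (length(bad)) {
        msg <- c(msg, sprintf("rule target gene(s) absent from DBN: %s",
                              paste(bad, collapse = ", ")))
      }
      bad <- setdiff(r$metabolite, met@metabolites$id)
      if (length(bad)) {
        msg <- c(msg, sprintf("rule metabolite(s) absent from metabolic model: %s",
                              paste(bad, collapse = ", ")))
      }
    }
  }
  bad <- setdiff(object@knockouts, nodes)
  if (length(bad)) {
    msg <- c(msg, sprintf("knocked-out gene(s) absent from DBN: %s",
                          paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Gene-state trajectory
#'
#' Per-gene, per-slice Gaussian activity states, either predicted forward from
#' the model or smoothed backward from phenotype evidence.
#'
#' @slot mean,sd numeric matrices, genes x slices (columns are time indices
#'   0..n as \code{t0, t1, ...}).
#' @slot times numeric vector of slice times in hours.
#' @slot direction \code{"forward"} or \code{"backward"}.
#' @export
setClass("GeneStateTrajectory",
  representation(
    mean = "matrix",
    sd = "matrix",
    times = "numeric",
    direction = "character"
  )
)

setValidity("GeneStateTrajectory", function(object) {
  msg <- character(0)
  if (!identical(dim(object@mean), dim(object@sd))) msg <- c(msg, "mean/sd dims differ")
  if (length(object@times) != ncol(object@mean)) msg <- c(msg, "times length != slice count")
  if (any(object@sd < 0)) msg <- c(msg, "negative state SD")
  if (!object@direction %in% c("forward", "backward")) {
    msg <- c(msg, "direction must be 'forward' or 'backward'")
  }
  if (length(msg)) msg else TRUE
})

#' Growth parameters of a (possibly biphasic) growth curve
#'
#' Descriptive parameters of one strain's OD curve: fermentative (pre-shift)
#' and respiratory (post-shift) specific growth rates in 1/h, the shift time
#' and lag in hours, the final yield in OD units, and whether a diauxic shift
#' was detected at all.
#'
#' @slot preRate,postRate specific growth rates (1/h), clipped at 0.
#' @slot shiftTime time of the fermentative-to-respiratory transition (h);
#'   \code{NA} when no candidate shift point could be located (significance
#'   of a located shift is carried by \code{shiftDetected}).
#' @slot lag time to exceed 1.05x the initial OD (h).
#' @slot yieldOD final OD of the curve.
#' @slot shiftDetected logical flag.
#' @export
setClass("GrowthParameters",
  representation(
    preRate = "numeric",
    postRate = "numeric",
    shiftTime = "numeric",
    lag = "numeric",
    yieldOD = "numeric",
    shiftDetected = "logical"
  )
)

setValidity("GrowthParameters", function(object) {
  msg <- character(0)
  if (!is.na(object@preRate) && object@preRate < 0) msg <- c(msg, "preRate < 0")
  if (!is.na(object@postRate) && object@postRate < 0) msg <- c(msg, "postRate < 0")
  if (length(msg)) msg else TRUE
})

#' Result of a coupled regulatory-metabolic simulation
#'
#' @slot trajectory the [GeneStateTrajectory-class] of the run.
#' @slot culture data.frame: \code{time_h}, \code{biomass} (gDW/L) and one
#'   column per medium metabolite (mM).
#' @slot fluxes numeric matrix, reactions x steps, the flux distribution used
#'   on each interval (column k covers (t_{k-1}, t_k]).
#' @slot ruleApplied logical matrix, genes x slices: which states were
#'   overwritten by metabolite rules.
#' @slot odFactor OD560 units per gDW/L, used when exporting predicted curves.
#' @slot growth the derived [GrowthParameters-class] of the predicted curve.
#' @export
setClass("SimulationResult",
  representation(
    trajectory = "GeneStateTrajectory",
    culture = "data.frame",
    fluxes = "matrix",
    ruleApplied = "matrix",
    odFactor = "numeric",
    growth = "GrowthParameters"
  )
)

setValidity("SimulationResult", function(object) {
  msg <- character(0)
  nt <- length(object@trajectory@times)
  if (nrow(object@culture) != nt) msg <- c(msg, "culture rows must match slice count")
  if (ncol(object@fluxes) && ncol(object@fluxes) != nt - 1L) {
    msg <- c(msg, "fluxes must have one column per step")
  }
  if (any(object@culture$biomass < 0)) msg <- c(msg, "negative biomass")
  if (length(msg)) msg else TRUE
})
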