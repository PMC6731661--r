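#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("genes", "RegulatoryDBN", function(x) x@nodes)
#' @rdname accessors
setMethod("genes", "HybridModel", function(x) x@regulatory@nodes)
#' @rdname accessors
setMethod("geneTypes", "RegulatoryDBN", function(x) x@nodeType[x@nodes])
#' @rdname accessors
setMethod("geneTypes", "HybridModel", function(x) geneTypes(x@regulatory))
#' @rdname accessors
setMethod("regulators", "RegulatoryDBN", function(x) x@nodes[x@nodeType[x@nodes] == "regulator"])
#' @rdname accessors
setMethod("regulators", "HybridModel", function(x) regulators(x@regulatory))
#' @rdname accessors
setMethod("enzymes", "RegulatoryDBN", function(x) x@nodes[x@nodeType[x@nodes] == "enzyme"])
#' @rdname accessors
setMethod("enzymes", "HybridModel", function(x) enzymes(x@regulatory))
#' @rdname accessors
setMethod("dbnEdges", "RegulatoryDBN", function(x) x@edges)
#' @rdname accessors
setMethod("dbnEdges", "HybridModel", function(x) x@regulatory@edges)
#' @rdname accessors
setMethod("knockouts", "HybridModel", function(x) x@knockouts)
#' @rdname accessors
setMethod("metaboliteRules", "HybridModel", function(x) x@rules)
#' @rdname accessors
setMethod("regulatoryPart", "HybridModel", function(x) x@regulatory)
#' @rdname accessors
setMethod("metabolicPart", "HybridModel", function(x) x@metabolic)
#' @rdname accessors
setMethod("reactionTable", "MetabolicModel", function(x) x@reactions)
#' @rdname accessors
setMethod("reactionTable", "HybridModel", function(x) x@metabolic@reactions)
#' @rdname accessors
setMethod("metaboliteTable", "MetabolicModel", function(x) x@metabolites)
#' @rdname accessors
setMethod("metaboliteTable", "HybridModel", function(x) x@metabolic@metabolites)
#' @rdname accessors
setMethod("biomassReaction", "MetabolicModel", function(x) x@biomassId)
#' @rdname accessors
setMethod("biomassReaction", "HybridModel", function(x) x@metabolic@biomassId)

#' @rdname trajectory-accessors
setMethod("stateMeans", "GeneStateTrajectory", function(x) x@mean)
#' @rdname trajectory-accessors
setMethod("stateSds", "GeneStateTrajectory", function(x) x@sd)
#' @rdname trajectory-accessors
setMethod("sliceTimes", "GeneStateTrajectory", function(x) x@times)
#' @rdname trajectory-accessors
setMethod("stateMeans", "SimulationResult", function(x) x@trajectory@mean)
#' @rdname trajectory-accessors
setMethod("stateSds", "SimulationResult", function(x) x@trajectory@sd)
#' @rdname trajectory-accessors
setMethod("sliceTimes", "SimulationResult", function(x) x@trajectory@times)

#' @rdname cultureSeries
setMethod("cultureSeries", "SimulationResult", function(x) x@culture)

#' @rdname growthParams
setMethod("growthParams", "SimulationResult", function(x) x@growth)
#' @rdname growthParams
setMethod("growthParams", "GrowthParameters", function(x) x)

setMethod("show", "RegulatoryDBN", function(object) {
  cat(sprintf("RegulatoryDBN: %d nodes (%d regulators, %d enzymes), %d edges\n",
              length(object@nodes), length(regulators(object)),
              length(enzymes(object)), nrow(object@edges)))
})

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites x %d reactions, biomass = '%s', %d gene rules\n",
              nrow(object@metabolites), nrow(object@reactions),
              object@biomassId, length(object@geneRules)))
})

setMethod("show", "HybridModel", function(object) {
  show(object@regulatory)
  show(object@metabolic)
  cat(sprintf("%d metabolite rules; knockouts: %s\n", nrow(object@rules),
              if (length(object@knockouts)) paste(object@knockouts, collapse = ", ") else "none"))
})

setMethod("show", "GeneStateTrajectory", function(object) {
  cat(sprintf("GeneStateTrajectory (%s): %d genes x %d slices, t = %.2g..%.2g h\n",
              object@direction, nrow(object@mean), ncol(object@mean),
              min(object@times), max(object@times)))
})

setMethod("show", "GrowthParameters", function(object) {
  cat(sprintf(
    "GrowthParameters: pre %.3f /h, post %.3f /h, shift %s h, lag %.2f h, yield %.3f OD, shift %s\n",
    object@preRate, object@postRate,
    if (is.na(object@shiftTime)) "NA" else sprintf("%.2f", object@shiftTime),
    object@lag, object@yieldOD,
    if (object@shiftDetected) "detected" else "not detected"))
})

setMethod("show", "SimulationResult", function(object) {
  show(object@trajectory)
  cat(sprintf("Culture: X %.3g -> %.3g gDW/L over %.1f h\n",
              object@culture$biomass[1],
              object@culture$biomass[nrow(object@culture)],
              max(object@trajectory@times)))
  show(object@growth)
})
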