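#' @include AllClasses.R
NULL

#' Accessors for hybrid-model components
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{genes()} returns node ids, \code{geneTypes()} the regulator/enzyme
#' tags, \code{regulators()}/\code{enzymes()} the respective subsets,
#' \code{dbnEdges()} the weighted edge table, \code{knockouts()} the deleted
#' genes, \code{metaboliteRules()} the metabolite-to-gene rule table, and
#' \code{regulatoryPart()}/\code{metabolicPart()} the two layers of a
#' [HybridModel-class].
#'
#' @param x a [HybridModel-class], [RegulatoryDBN-class] or
#'   [MetabolicModel-class] as appropriate.
#' @return See each generic's description.
#' @name accessors
#' @aliases genes geneTypes regulators enzymes dbnEdges knockouts
#'   metaboliteRules regulatoryPart metabolicPart reactionTable
#'   metaboliteTable biomassReaction
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("geneTypes", function(x) standardGeneric("geneTypes"))
#' @rdname accessors
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))
#' @rdname accessors
#' @export
setGeneric("enzymes", function(x) standardGeneric("enzymes"))
#' @rdname accessors
#' @export
setGeneric("dbnEdges", function(x) standardGeneric("dbnEdges"))
#' @rdname accessors
#' @export
setGeneric("knockouts", function(x) standardGeneric("knockouts"))
#' @rdname accessors
#' @export
setGeneric("metaboliteRules", function(x) standardGeneric("metaboliteRules"))
#' @rdname accessors
#' @export
setGeneric("regulatoryPart", function(x) standardGeneric("regulatoryPart"))
#' @rdname accessors
#' @export
setGeneric("metabolicPart", function(x) standardGeneric("metabolicPart"))
#' @rdname accessors
#' @export
setGeneric("reactionTable", function(x) standardGeneric("reactionTable"))
#' @rdname accessors
#' @export
setGeneric("metaboliteTable", function(x) standardGeneric("metaboliteTable"))
#' @rdname accessors
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))

#' Extract growth parameters from simulation and phenotyping results
#'
#' @param x a [SimulationResult-class] or [GrowthParameters-class] carrier.
#' @export
setGeneric("growthParams", function(x) standardGeneric("growthParams"))

#' State matrices of a trajectory
#'
#' \code{stateMeans()} and \code{stateSds()} return genes x slices matrices.
#'
#' @param x a [GeneStateTrajectory-class] or [SimulationResult-class].
#' @name trajectory-accessors
NULL

#' @rdname trajectory-accessors
#' @export
setGeneric("stateMeans", function(x) standardGeneric("stateMeans"))
#' @rdname trajectory-accessors
#' @export
setGeneric("stateSds", function(x) standardGeneric("stateSds"))
#' @rdname trajectory-accessors
#' @export
setGeneric("sliceTimes", function(x) standardGeneric("sliceTimes"))

#' Predicted culture time course of a simulation
#'
#' @param x a [SimulationResult-class].
#' @return data.frame with \code{time_h}, \code{biomass} and medium
#'   concentrations.
#' @export
setGeneric("cultureSeries", function(x) standardGeneric("cultureSeries"))
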