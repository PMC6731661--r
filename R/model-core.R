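#' @include AllClasses.R rules.R
NULL

#' Construct a regulatory DBN
#'
#' @param nodes character vector of gene ids.
#' @param types character vector (recycled names ok): \code{"regulator"} or
#'   \code{"enzyme"} per node.
#' @param edges data.frame with \code{parent}, \code{child}, \code{weight}
#'   (may be empty / NULL).
#' @param bias,sigma,initMean,initSd numerics named by node (unnamed scalars
#'   are recycled to all nodes).
#' @return a validated [RegulatoryDBN-class].
#' @examples
#' dbn <- regulatoryDBN(c("R1", "E1"), c("regulator", "enzyme"),
#'                      data.frame(parent = "R1", child = "E1", weight = 0.9),
#'                      bias = c(R1 = 0.5, E1 = 0), sigma = 0.05)
#' @export
regulatoryDBN <- function(nodes, types, edges = NULL, bias = 0, sigma = 0.05,
                          initMean = 0, initSd = 0) {
  expand <- function(v) {
    if (is.null(names(v)) && length(v) %in% c(1L, length(nodes))) {
      return(setNames(rep_len(as.numeric(v), length(nodes)), nodes))
    }
    out <- setNames(rep(0, length(nodes)), nodes)
    out[names(v)] <- v
    out
  }
  if (is.null(edges)) {
    edges <- data.frame(parent = character(0), child = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  obj <- new("RegulatoryDBN",
             nodes = nodes,
             nodeType = setNames(rep_len(types, length(nodes)), nodes),
             edges = edges,
             bias = expand(bias), sigma = expand(sigma),
             initMean = expand(initMean), initSd = expand(initSd))
  validObject(obj)
  obj
}

#' Construct a metabolic model
#'
#' @param metabolites data.frame with \code{id} and optional \code{external},
#'   \code{buffered}, \code{carbon} columns.
#' @param reactions data.frame with \code{id}, \code{lb}, \code{ub} and a
#'   \code{stoichiometry} list-column of named coefficient vectors (negative =
#'   consumed).
#' @param biomassId id of the growth reaction (its flux is mu in 1/h).
#' @param exchangeIds ids of exchange reactions.
#' @param geneRules named character vector or list of rule strings per
#'   reaction (parsed with [parseGeneRule()]).
#' @param uptakeKinetics data.frame \code{metabolite}, \code{exchange},
#'   \code{vmax}, \code{km} (may be empty).
#' @return a validated [MetabolicModel-class].
#' @export
metabolicModel <- function(metabolites, reactions, biomassId, exchangeIds,
                           geneRules = list(), uptakeKinetics = NULL) {
  if (is.null(metabolites[["external"]])) metabolites$external <- FALSE
  if (is.null(metabolites[["buffered"]])) metabolites$buffered <- FALSE
  if (is.null(metabolites[["carbon"]])) metabolites$carbon <- 0
  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  for (j in seq_len(nrow(reactions))) {
    st <- reactions$stoichiometry[[j]]
    if (length(st)) S[names(st), j] <- st
  }
  rxn <- data.frame(id = reactions$id, lb = reactions$lb, ub = reactions$ub,
                    reversible = reactions$lb < 0, stringsAsFactors = FALSE)
  rules <- lapply(geneRules, function(r) if (is.character(r)) parseGeneRule(r) else r)
  if (is.null(uptakeKinetics)) {
    uptakeKinetics <- data.frame(metabolite = character(0), exchange = character(0),
                                 vmax = numeric(0), km = numeric(0))
  }
  obj <- new("MetabolicModel", stoich = S,
             metabolites = metabolites[c("id", "external", "buffered", "carbon")],
             reactions = rxn, biomassId = biomassId,
             exchangeIds = exchangeIds, geneRules = rules,
             uptakeKinetics = uptakeKinetics)
  validObject(obj)
  obj
}

#' Assemble a hybrid model
#'
#' @param regulatory a [RegulatoryDBN-class].
#' @param metabolic a [MetabolicModel-class].
#' @param rules metabolite-to-gene rule data.frame (columns
#'   \code{metabolite}, \code{comparator} in \code{c("lt", "ge")},
#'   \code{threshold}, \code{target}, \code{mean}, \code{sd}); NULL for none.
#' @param knockouts character vector of deleted genes.
#' @return a validated [HybridModel-class].
#' @export
hybridModel <- function(regulatory, metabolic, rules = NULL, knockouts = character(0)) {
  if (is.null(rules)) {
    rules <- data.frame(metabolite = character(0), comparator = character(0),
                        threshold = numeric(0), target = character(0),
                        mean = numeric(0), sd = numeric(0), stringsAsFactors = FALSE)
  }
  obj <- new("HybridModel", regulatory = regulatory, metabolic = metabolic,
             rules = rules, knockouts = knockouts)
  validObject(obj)
  obj
}

#' Apply gene knockouts to a hybrid model
#'
#' Returns a copy of the model whose knockout set is extended by \code{genes}.
#' During simulation every knocked-out gene is clamped to state (0, 0) at all
#' slices and its literal in any gene-reaction rule evaluates to 0, so a
#' deletion severs both the signal flow and the mass flow it gates.
#' Idempotent and commutative over gene sets.
#'
#' @param model a [HybridModel-class].
#' @param genes character vector of gene ids to delete (may be empty).
#' @return the modified model.
#' @export
applyKnockout <- function(model, genes) {
  if (!length(genes)) return(model)
  unknown <- setdiff(genes, genes(model))
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  model@knockouts <- sort(unique(c(model@knockouts, genes)))
  model
}

#' Validate a hybrid model without raising
#'
#' Collects every invariant violation of the model and its two layers into a
#' report instead of stopping on the first one. S4 validity machinery is
#' reused, so [validateModel()] and object construction enforce the same
#' rules.
#'
#' @param model a [HybridModel-class] (possibly constructed from untrusted
#'   input via \code{validate = FALSE} paths or JSON editing).
#' @return character vector of violations; empty when the model is valid.
#' @export
validateModel <- function(model) {
  msgs <- character(0)
  collect <- function(obj) {
    v <- tryCatch(getValidity(getClass(class(obj)))(obj), error = function(e) conditionMessage(e))
    if (!isTRUE(v)) msgs <<- c(msgs, v)
  }
  collect(model@regulatory)
  collect(model@metabolic)
  collect(model)
  unname(msgs)
}
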