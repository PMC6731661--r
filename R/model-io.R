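#' @include model-core.R
NULL

MODEL_SCHEMA_VERSION <- "1.0"

#' Load / save a hybrid model
#'
#' The interchange format is a versioned JSON document holding the complete
#' hybrid model in one artifact:
#' \preformatted{
#' {
#'   "model_version": "1.0",
#'   "regulatory": {
#'     "nodes":        [{"id", "type"}, ...],
#'     "edges":        [{"parent", "child", "weight"}, ...],
#'     "conditionals": {"<gene>": {"bias", "sigma", "init_mean", "init_sd"}}
#'   },
#'   "metabolic": {
#'     "metabolites":     [{"id", "external", "buffered", "carbon"}, ...],
#'     "reactions":       [{"id", "lb", "ub", "stoichiometry": {met: coef}}, ...],
#'     "biomass_reaction": "<id>",
#'     "exchanges":        ["<id>", ...],
#'     "gene_rules":       {"<reaction>": "<boolean rule>"},
#'     "uptake_kinetics":  [{"metabolite", "exchange", "vmax", "km"}, ...]
#'   },
#'   "rules":      [{"metabolite", "comparator", "threshold_mM",
#'                   "target", "mean", "sd"}, ...],
#'   "knocked_out": ["<gene>", ...]
#' }
#' }
#' \code{comparator} is \code{"<"} or \code{">="}. Saving then loading is
#' lossless, and saving a loaded file reproduces it byte for byte.
#'
#' For the metabolic part alone, [readSBMLMetabolic()] imports standard SBML
#' (level 3 with fbc flux bounds and gene-product associations) and maps it
#' onto the same representation; pass the result to [hybridModel()] together
#' with a regulatory JSON part.
#'
#' @param path file path.
#' @param model a [HybridModel-class].
#' @return \code{loadHybridModel}: a validated [HybridModel-class];
#'   \code{saveHybridModel}: \code{path}, invisibly.
#' @export
loadHybridModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("model file does not parse as JSON: ",
                                           conditionMessage(e), call. = FALSE))
  for (key in c("regulatory", "metabolic")) {
    if (is.null(doc[[key]])) stop("model file is missing required element '", key, "'")
  }
  reg <- doc$regulatory
  nodes <- vapply(reg$nodes, function(x) x$id, "")
  types <- vapply(reg$nodes, function(x) x$type, "")
  edges <- if (length(reg$edges)) {
    data.frame(parent = vapply(reg$edges, function(e) e$parent, ""),
               child = vapply(reg$edges, function(e) e$child, ""),
               weight = vapply(reg$edges, function(e) as.numeric(e$weight), 0),
               stringsAsFactors = FALSE)
  } else NULL
  cond <- reg$conditionals
  getc <- function(field, default = 0) {
    vapply(nodes, function(g) as.numeric(cond[[g]][[field]] %||% default), 0)
  }
  dbn <- tryCatch(
    regulatoryDBN(nodes, types, edges,
                  bias = getc("bias"), sigma = getc("sigma"),
                  initMean = getc("init_mean"), initSd = getc("init_sd")),
    error = function(e) stop("invalid regulatory part: ", conditionMessage(e), call. = FALSE))

  mb <- doc$metabolic
  mets <- data.frame(
    id = vapply(mb$metabolites, function(m) m$id, ""),
    external = vapply(mb$metabolites, function(m) isTRUE(m$external), TRUE),
    buffered = vapply(mb$metabolites, function(m) isTRUE(m$buffered), TRUE),
    carbon = vapply(mb$metabolites, function(m) as.numeric(m$carbon %||% 0), 0),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = vapply(mb$reactions, function(r) r$id, ""),
    lb = vapply(mb$reactions, function(r) as.numeric(r$lb), 0),
    ub = vapply(mb$reactions, function(r) as.numeric(r$ub), 0),
    stringsAsFactors = FALSE)
  rxns$stoichiometry <- lapply(mb$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    if (is.null(st)) numeric(0) else st
  })
  kin <- if (length(mb$uptake_kinetics)) {
    data.frame(metabolite = vapply(mb$uptake_kinetics, function(k) k$metabolite, ""),
               exchange = vapply(mb$uptake_kinetics, function(k) k$exchange, ""),
               vmax = vapply(mb$uptake_kinetics, function(k) as.numeric(k$vmax), 0),
               km = vapply(mb$uptake_kinetics, function(k) as.numeric(k$km), 0),
               stringsAsFactors = FALSE)
  } else NULL
  met <- tryCatch(
    metabolicModel(mets, rxns,
                   biomassId = mb$biomass_reaction %||% stop("missing biomass_reaction"),
                   exchangeIds = unlist(mb$exchanges) %||% character(0),
                   geneRules = lapply(mb$gene_rules, identity),
                   uptakeKinetics = kin),
    error = function(e) stop("invalid metabolic part: ", conditionMessage(e), call. = FALSE))

  rules <- if (length(doc$rules)) {
    data.frame(
      metabolite = vapply(doc$rules, function(r) r$metabolite, ""),
      comparator = vapply(doc$rules, function(r) {
        cmp <- r$comparator
        if (cmp == "<") "lt" else if (cmp == ">=") "ge"
        else stop("rule comparator must be '<' or '>=': got '", cmp, "'")
      }, ""),
      threshold = vapply(doc$rules, function(r) as.numeric(r$threshold_mM), 0),
      target = vapply(doc$rules, function(r) r$target, ""),
      mean = vapply(doc$rules, function(r) as.numeric(r$mean), 0),
      sd = vapply(doc$rules, function(r) as.numeric(r$sd), 0),
      stringsAsFactors = FALSE)
  } else NULL
  ko <- as.character(unlist(doc$knocked_out) %||% character(0))

  model <- new("HybridModel", regulatory = dbn, metabolic = met,
               rules = rules %||% data.frame(metabolite = character(0),
                                             comparator = character(0),
                                             threshold = numeric(0),
                                             target = character(0),
                                             mean = numeric(0), sd = numeric(0),
                                             stringsAsFactors = FALSE),
               knockouts = ko)
  bad <- validateModel(model)
  if (length(bad)) {
    stop("model file violates invariants:\n  - ", paste(bad, collapse = "\n  - "))
  }
  model
}

#' @rdname loadHybridModel
#' @export
saveHybridModel <- function(model, path) {
  dbn <- model@regulatory
  met <- model@metabolic
  nodes <- lapply(dbn@nodes, function(g) list(id = g, type = unname(dbn@nodeType[[g]])))
  edges <- lapply(seq_len(nrow(dbn@edges)), function(i) {
    list(parent = dbn@edges$parent[i], child = dbn@edges$child[i],
         weight = dbn@edges$weight[i])
  })
  cond <- setNames(lapply(dbn@nodes, function(g) {
    list(bias = unname(dbn@bias[[g]]), sigma = unname(dbn@sigma[[g]]),
         init_mean = unname(dbn@initMean[[g]]), init_sd = unname(dbn@initSd[[g]]))
  }), dbn@nodes)
  mets <- lapply(seq_len(nrow(met@metabolites)), function(i) {
    m <- met@metabolites[i, ]
    list(id = m$id, external = m$external, buffered = m$buffered, carbon = m$carbon)
  })
  rxns <- lapply(seq_len(nrow(met@reactions)), function(j) {
    st <- met@stoich[, j]
    st <- st[st != 0]
    list(id = met@reactions$id[j], lb = met@reactions$lb[j],
         ub = met@reactions$ub[j], stoichiometry = as.list(st))
  })
  kin <- lapply(seq_len(nrow(met@uptakeKinetics)), function(i) {
    k <- met@uptakeKinetics[i, ]
    list(metabolite = k$metabolite, exchange = k$exchange, vmax = k$vmax, km = k$km)
  })
  rules <- lapply(seq_len(nrow(model@rules)), function(i) {
    r <- model@rules[i, ]
    list(metabolite = r$metabolite,
         comparator = if (r$comparator == "lt") "<" else ">=",
         threshold_mM = r$threshold, target = r$target, mean = r$mean, sd = r$sd)
  })
  doc <- list(
    model_version = MODEL_SCHEMA_VERSION,
    regulatory = list(nodes = nodes, edges = edges, conditionals = cond),
    metabolic = list(
      metabolites = mets, reactions = rxns,
      biomass_reaction = met@biomassId,
      exchanges = as.list(met@exchangeIds),
      gene_rules = setNames(lapply(met@geneRules, deparseGeneRule), names(met@geneRules)),
      uptake_kinetics = kin),
    rules = rules,
    knocked_out = as.list(model@knockouts))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2)
  writeLines(json, path)
  invisible(path)
}

#' Import the metabolic part of a hybrid model from SBML
#'
#' Reads standard SBML (level 3; fbc package flux bounds and gene-product
#' associations are honoured when present) and returns a
#' [MetabolicModel-class]. Boundary-condition species are treated as medium
#' (external) metabolites; reactions touching only boundary species on one
#' side, or flagged by the conventional \code{EX_} prefix, are taken as
#' exchanges. Uptake kinetics are not part of SBML and default to an empty
#' table.
#'
#' @param path SBML file path.
#' @param biomassId biomass reaction id; if NULL the first reaction whose id
#'   contains "biomass" (case-insensitive) is used.
#' @return a [MetabolicModel-class].
#' @export
readSBMLMetabolic <- function(path, biomassId = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(spNodes)) stop("no species found in SBML file: ", path)
  mets <- data.frame(
    id = xml2::xml_attr(spNodes, "id"),
    external = xml2::xml_attr(spNodes, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  # parameter table for fbc bound references
  parNodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pars <- setNames(as.numeric(xml2::xml_attr(parNodes, "value")),
                   xml2::xml_attr(parNodes, "id"))
  rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxNodes)) stop("no reactions found in SBML file: ", path)
  big <- 1000
  rid <- xml2::xml_attr(rxNodes, "id")
  rxns <- data.frame(id = rid, lb = NA_real_, ub = NA_real_, stringsAsFactors = FALSE)
  rxns$stoichiometry <- vector("list", length(rid))
  rules <- list()
  for (j in seq_along(rxNodes)) {
    rx <- rxNodes[[j]]
    rev <- !(xml2::xml_attr(rx, "reversible") %in% "false")
    lbRef <- xml2::xml_attr(rx, "lowerFluxBound")
    ubRef <- xml2::xml_attr(rx, "upperFluxBound")
    rxns$lb[j] <- if (!is.na(lbRef) && lbRef %in% names(pars)) pars[[lbRef]] else if (rev) -big else 0
    rxns$ub[j] <- if (!is.na(ubRef) && ubRef %in% names(pars)) pars[[ubRef]] else big
    st <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx, paste0("./", tag, "/speciesReference"))
      if (length(refs)) {
        sp <- xml2::xml_attr(refs, "species")
        coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        coef[is.na(coef)] <- 1
        for (k in seq_along(sp)) {
          cur <- if (sp[k] %in% names(st)) st[[sp[k]]] else 0
          st[[sp[k]]] <- cur + side * coef[k]
        }
      }
    }
    rxns$stoichiometry[[j]] <- st
    gpa <- xml2::xml_find_first(rx, ".//geneProductAssociation")
    if (!inherits(gpa, "xml_missing")) {
      rules[[rid[j]]] <- sbmlGeneAssociation(gpa)
    }
  }
  # drop boundary species from the stoichiometry (they are not balanced)
  bnd <- mets$id[mets$external]
  rxns$stoichiometry <- lapply(rxns$stoichiometry, function(st) st[!(names(st) %in% bnd)])
  keep <- !(mets$id %in% bnd)
  metsKeep <- data.frame(id = mets$id[keep], external = FALSE, stringsAsFactors = FALSE)
  exch <- rid[grepl("^EX_", rid) |
                vapply(rxns$stoichiometry, function(st) length(st) <= 1L, TRUE)]
  if (is.null(biomassId)) {
    hit <- rid[grepl("biomass", rid, ignore.case = TRUE)]
    if (!length(hit)) stop("cannot identify a biomass reaction; pass biomassId")
    biomassId <- hit[1]
  }
  geneIds <- unique(unlist(lapply(rules, ruleGenes)))
  metabolicModel(metsKeep, rxns, biomassId = biomassId,
                 exchangeIds = setdiff(exch, biomassId),
                 geneRules = lapply(rules, deparseGeneRule))
}

# fbc geneProductAssociation -> rule string
sbmlGeneAssociation <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "geneProductAssociation") {
    kids <- xml2::xml_children(node)
    return(sbmlGeneAssociation(kids[[1]]))
  }
  if (name == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(list(op = "gene", gene = g))
  }
  if (name %in% c("and", "or")) {
    args <- lapply(xml2::xml_children(node), sbmlGeneAssociation)
    return(list(op = name, args = args))
  }
  stop("unsupported gene association element: ", name)
}
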