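# Domain types, serialization, validation, knockouts.

test_that("a minimal one-regulator/one-enzyme model is legal", {
  m <- toyChainModel()
  expect_s4_class(m, "HybridModel")
  expect_length(genes(m), 2)
  expect_identical(validateModel(m), character(0))
})

test_that("enzymes cannot have children", {
  expect_error(
    regulatoryDBN(c("R1", "E1"), c("regulator", "enzyme"),
                  data.frame(parent = "E1", child = "R1", weight = 1)),
    "enzyme cannot have children")
})

test_that("invariant violations are collected, not raised, by validateModel", {
  m <- toyChainModel()
  dbn <- regulatoryPart(m)
  dbn@sigma[["R1"]] <- -1           # bypass constructor on purpose
  m@regulatory <- dbn
  m@rules <- data.frame(metabolite = "glc_e", comparator = "lt", threshold = 0.5,
                        target = "NOPE", mean = 1, sd = 0.1)
  rep <- validateModel(m)
  expect_true(any(grepl("negative noise SD", rep)))
  expect_true(any(grepl("NOPE", rep)))
})

test_that("model JSON round-trips losslessly and byte-identically", {
  m <- cachedTruth(seed = 1)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  saveHybridModel(m, f1)
  m2 <- loadHybridModel(f1)
  saveHybridModel(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(dbnEdges(m2), dbnEdges(m))
  expect_equal(m2@regulatory@bias, m@regulatory@bias)
  expect_equal(m2@metabolic@stoich, m@metabolic@stoich)
  expect_equal(metaboliteRules(m2), metaboliteRules(m))
})

test_that("serialization round-trip is lossless over many generated models", {
  for (s in seq(2, 20, by = 2)) {
    m <- generateGroundTruth(labConfig(seed = s, nRegulators = 9, nEnzymes = 5))
    f <- tempfile(fileext = ".json")
    saveHybridModel(m, f)
    m2 <- loadHybridModel(f)
    expect_equal(dbnEdges(m2), dbnEdges(m), info = paste("seed", s))
    expect_equal(m2@regulatory@sigma, m@regulatory@sigma)
    expect_identical(validateModel(m2), character(0))
  }
})

test_that("loading rejects files with broken invariants, naming the fault", {
  m <- toyChainModel()
  f <- tempfile(fileext = ".json")
  saveHybridModel(m, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc$regulatory$edges[[1]] <- list(parent = "E1", child = "R1", weight = 1)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f)
  expect_error(loadHybridModel(f), "enzyme cannot have children")
  expect_error(loadHybridModel(tempfile()), "not found")
})

test_that("apply_knockout is idempotent, commutative, and validates gene ids", {
  m <- cachedTruth(seed = 1)
  expect_identical(applyKnockout(m, character(0)), m)
  a <- applyKnockout(applyKnockout(m, "MIG1"), c("HAP4", "MIG1"))
  b <- applyKnockout(applyKnockout(m, "HAP4"), "MIG1")
  expect_identical(knockouts(a), knockouts(b))
  expect_error(applyKnockout(m, "NOT_A_GENE"), "unknown gene")
})

test_that("knocked-out genes are clamped to (0,0) and close their reactions", {
  m <- cachedTruth(seed = 1)
  sim <- simulateStrain(applyKnockout(m, "HAP4"), horizon = 10, dt = 0.5)
  expect_true(all(stateMeans(sim)["HAP4", ] == 0))
  expect_true(all(stateSds(sim)["HAP4", ] == 0))
  # sole uptake enzyme knocked out -> biomass stays at the inoculum
  sim2 <- simulateStrain(applyKnockout(m, "HXT1"), horizon = 20, dt = 0.5)
  X <- cultureSeries(sim2)$biomass
  expect_lt(max(X) / X[1], 1.001)
})

test_that("gene rules parse, evaluate fuzzily, and survive deparse", {
  r <- parseGeneRule("(A and B) or C")
  expect_equal(evalGeneRule(r, c(A = 0.8, B = 0.2, C = 0.1)), 0.2)
  expect_equal(evalGeneRule(r, c(A = 0.8, B = 0.2, C = 0.9)), 0.9)
  expect_equal(evalGeneRule(r, c(A = 0.8, B = 0.9, C = 0), knockouts = "B"), 0)
  expect_equal(evalGeneRule(parseGeneRule(deparseGeneRule(r)),
                            c(A = 1, B = 0.5, C = 0.2)), 0.5)
  expect_error(parseGeneRule("A and (B or"), "unbalanced|unexpectedly")
})

test_that("metabolite rules fire on threshold crossings in file order", {
  rules <- data.frame(metabolite = c("glc_e", "glc_e"), comparator = c("ge", "lt"),
                      threshold = c(0.75, 0.75), target = c("CAT8", "CAT8"),
                      mean = c(0, 1), sd = c(0.02, 0.05))
  expect_equal(firingRules(rules, c(glc_e = 10))$mean, 0)
  expect_equal(firingRules(rules, c(glc_e = 0.1))$mean, 1)
  expect_equal(nrow(firingRules(rules[0, ], c(glc_e = 1))), 0)
})

test_that("SBML fbc import maps onto the same metabolic representation", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy">',
    '<listOfParameters>',
    '<parameter id="lb0" value="0"/><parameter id="ub10" value="10"/>',
    '<parameter id="lbm10" value="-10"/><parameter id="ub100" value="100"/>',
    '</listOfParameters>',
    '<listOfSpecies>',
    '<species id="glc_i" boundaryCondition="false"/>',
    '<species id="glc_b" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_glc" reversible="true" lowerFluxBound="lbm10" upperFluxBound="ub10">',
    '<listOfProducts><speciesReference species="glc_i" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="biomass_rxn" reversible="false" lowerFluxBound="lb0" upperFluxBound="ub100">',
    '<listOfReactants><speciesReference species="glc_i" stoichiometry="2"/></listOfReactants>',
    '<geneProductAssociation><and>',
    '<geneProductRef geneProduct="E1"/><geneProductRef geneProduct="E2"/>',
    '</and></geneProductAssociation>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  met <- readSBMLMetabolic(f)
  expect_s4_class(met, "MetabolicModel")
  expect_equal(met@biomassId, "biomass_rxn")
  expect_equal(met@stoich["glc_i", "biomass_rxn"], -2)
  expect_equal(reactionTable(met)$lb[reactionTable(met)$id == "EX_glc"], -10)
  expect_equal(sort(ruleGenes(met@geneRules$biomass_rxn)), c("E1", "E2"))
})
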