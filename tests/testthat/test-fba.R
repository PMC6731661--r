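# LP correctness, gene-to-bound coupling, fixed-growth inverse mode.

test_that("the toy chain LP has the hand-computed optimum", {
  m <- toyChainModel(uptakeUb = 10, yield = 0.5)
  sol <- solveFBA(metabolicPart(m))
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$fluxes[["UPT"]]), 10)
  expect_equal(sol$objective, 5)   # 0.5 biomass per glucose
  # objective closed -> zero growth
  b <- defaultBounds(metabolicPart(m))
  b$ub[b$id == "BIO"] <- 0
  expect_equal(solveFBA(metabolicPart(m), b)$objective, 0)
  # inconsistent bounds are a precondition error
  b$lb[b$id == "UPT"] <- 5; b$ub[b$id == "UPT"] <- 1
  expect_error(solveFBA(metabolicPart(m), b), "lb > ub|inconsistent")
})

test_that("FBA optima match brute-force vertex enumeration on random toy LPs", {
  met <- metabolicPart(cachedTruth(seed = 1))
  S <- met@stoich
  set.seed(7)
  for (i in 1:40) {
    lb <- met@reactions$lb * runif(ncol(S), 0.2, 1)
    ub <- met@reactions$ub * runif(ncol(S), 0.2, 1)
    b <- data.frame(id = met@reactions$id, lb = lb, ub = ub)
    mine <- solveFBA(met, b)
    orc <- oracleLP(as.numeric(met@reactions$id == met@biomassId), S, lb, ub)
    expect_equal(mine$objective, orc$value, tolerance = 1e-7, info = paste("case", i))
  }
})

test_that("every flux distribution satisfies S v = 0 and its bounds", {
  met <- metabolicPart(cachedTruth(seed = 2))
  sol <- solveFBA(met, pfba = TRUE)
  expect_lt(max(abs(met@stoich %*% sol$fluxes)), 1e-9)
  b <- defaultBounds(met)
  expect_true(all(sol$fluxes >= b$lb - 1e-9 & sol$fluxes <= b$ub + 1e-9))
})

test_that("parsimonious tie-break removes futile flux from degenerate optima", {
  # two parallel uptake routes (OR isoenzymes): plain max growth is degenerate,
  # pFBA splits deterministically and minimally
  mets <- data.frame(id = c("s_e", "s_i"), external = c(TRUE, FALSE),
                     buffered = FALSE, carbon = 6)
  rx <- data.frame(id = c("U1", "U2", "BIO", "EX_s", "LOOP"),
                   lb = c(0, 0, 0, -10, -5), ub = c(10, 10, 100, 0, 5))
  rx$stoichiometry <- list(c(s_e = -1, s_i = 1), c(s_e = -1, s_i = 1),
                           c(s_i = -2), c(s_e = -1), c(s_i = 0))
  met <- metabolicModel(mets, rx, "BIO", "EX_s")
  sol <- solveFBA(met, pfba = TRUE)
  expect_equal(sol$objective, 5)
  expect_equal(unname(sol$fluxes[["LOOP"]]), 0)   # futile cycle suppressed
  expect_equal(unname(sol$fluxes[["U1"]] + sol$fluxes[["U2"]]), 10, tolerance = 1e-8)
})

test_that("gene states scale rule-bearing reaction bounds linearly", {
  met <- metabolicPart(cachedTruth(seed = 1))
  g <- genes(cachedTruth(seed = 1))
  ones <- geneStateSlice(setNames(rep(1, length(g)), g), setNames(rep(0, length(g)), g))
  expect_equal(geneStatesToBounds(met, ones), defaultBounds(met))
  # AND rule by hand
  mets <- data.frame(id = "x", external = FALSE, buffered = FALSE, carbon = 0)
  rx <- data.frame(id = c("R", "EX"), lb = c(-2, -10), ub = c(4, 10))
  rx$stoichiometry <- list(c(x = 1), c(x = -1))
  met2 <- metabolicModel(mets, rx, "R", "EX", geneRules = list(R = "g1 and g2"))
  s <- geneStateSlice(c(g1 = 0.8, g2 = 0.2), c(g1 = 0, g2 = 0))
  b <- geneStatesToBounds(met2, s)
  expect_equal(b$lb[b$id == "R"], -2 * 0.2)
  expect_equal(b$ub[b$id == "R"], 4 * 0.2)
  # knocked-out sole gene closes the reaction
  b0 <- geneStatesToBounds(met2, s, knockouts = c("g1"))
  expect_equal(b0$ub[b0$id == "R"], 0)
  # means above 1 are clipped before scaling
  s2 <- geneStateSlice(c(g1 = 1.7, g2 = 2), c(g1 = 0, g2 = 0))
  expect_equal(geneStatesToBounds(met2, s2)$ub[1], 4)
})

test_that("fixed-growth evidence: unique flux pins activity, slack spreads it", {
  m <- toyChainModel(uptakeUb = 10, yield = 0.5)
  met <- metabolicPart(m)
  # forced to the maximum: uptake uniquely 10 -> activity 1, SD at the floor
  ev <- boundsFromGrowth(met, 5)
  expect_true(ev$feasible)
  e1 <- ev$evidence[ev$evidence$gene == "E1", ]
  expect_equal(e1$mean, 1, tolerance = 1e-6)
  expect_equal(e1$sd, 0.05)
  # at mu = 0 no flux is required anywhere
  ev0 <- boundsFromGrowth(met, 0)
  expect_equal(ev0$evidence$mean, 0, tolerance = 1e-9)
  # infeasible growth rates fall back to the maximum with a warning
  expect_warning(ev2 <- boundsFromGrowth(met, 50), "exceeds")
  expect_false(ev2$feasible)
  expect_equal(ev2$mu, 5, tolerance = 1e-6)
})

test_that("parallel OR isoenzymes at half load give midpoint evidence 0.5", {
  mets <- data.frame(id = c("s_e", "s_i"), external = c(TRUE, FALSE),
                     buffered = FALSE, carbon = 6)
  rx <- data.frame(id = c("U1", "U2", "BIO", "EX_s"),
                   lb = c(0, 0, 0, -20), ub = c(10, 10, 100, 0))
  rx$stoichiometry <- list(c(s_e = -1, s_i = 1), c(s_e = -1, s_i = 1),
                           c(s_i = -1), c(s_e = -1))
  met <- metabolicModel(mets, rx, "BIO", "EX_s",
                        geneRules = list(U1 = "gA", U2 = "gB"))
  ev <- boundsFromGrowth(met, 10)  # half of the 20 max
  for (g in c("gA", "gB")) {
    row <- ev$evidence[ev$evidence$gene == g, ]
    expect_equal(row$mean, 0.5, tolerance = 1e-6, info = g)
    expect_equal(row$aMin, 0, tolerance = 1e-6)
    expect_equal(row$aMax, 1, tolerance = 1e-6)
  }
})

test_that("flux variability brackets every optimum found by enumeration", {
  met <- metabolicPart(cachedTruth(seed = 3))
  fv <- fluxVariability(met, c("GLCupt", "RESP"),
                        fix = setNames(0.2, biomassReaction(met)))
  expect_true(all(fv$min <= fv$max + 1e-9))
  orcMin <- oracleLP(as.numeric(met@reactions$id == "GLCupt"), met@stoich,
                     pmin2 <- pmax(met@reactions$lb, ifelse(met@reactions$id == "BIOMASS", 0.2 - 1e-9, met@reactions$lb)),
                     ifelse(met@reactions$id == "BIOMASS", 0.2 + 1e-9, met@reactions$ub),
                     maximize = FALSE)
  expect_equal(fv$min[fv$id == "GLCupt"], orcMin$value, tolerance = 1e-5)
})
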