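# Ensemble structure inference: dependency graphs, ranking, forward selection.

test_that("lagged dependency weights are |r| with self-edges excluded", {
  set.seed(4)
  n <- 200
  p <- rnorm(n)
  child <- c(0, p[-n]) * -0.9 + rnorm(n, 0, 0.1)   # anti-correlated lagged copy
  dat <- rbind(P = p, C = child, Z = rnorm(n))
  dg <- dependencyGraph(dat, c("P", "Z"))
  expect_false(any(dg$parent == dg$child))
  wPC <- dg$weight[dg$parent == "P" & dg$child == "C"]
  expect_equal(wPC, abs(cor(p[-n], child[-1])), tolerance = 1e-10)
  expect_gt(wPC, 0.9)
  # exact lagged copy scores 1
  dat2 <- rbind(A = p, B = c(0, p[-n]))
  expect_equal(dependencyGraph(dat2, "A")$weight[1], 1, tolerance = 1e-6)
  # zero-variance gene: weight 0 with a warning
  dat3 <- rbind(A = p, K = rep(1, n))
  expect_warning(dg3 <- dependencyGraph(dat3, c("A", "K")), "zero-variance")
  expect_equal(dg3$weight[dg3$parent == "K"], 0)
})

test_that("independent noise genes stay below 0.1 at n = 1000", {
  set.seed(11)
  dat <- matrix(rnorm(6000), 6, 1000,
                dimnames = list(sprintf("N%d", 1:6), NULL))
  dg <- dependencyGraph(dat, rownames(dat))
  expect_lt(max(dg$weight), 0.1)
})

test_that("K = 1 without subsampling is a single arborescence at f = 1", {
  truth <- cachedTruth(seed = 5, nRegulators = 9, nEnzymes = 5)
  dat <- generateExpressionDataset(truth, labConfig(seed = 5, nRegulators = 9,
                                                    nEnzymes = 5, nExprPoints = 80))
  rk <- ensembleRank(dat, prior = NULL, K = 1, rowFrac = 1, nodeFrac = 1,
                     candidates = regulators(truth), wMin = 0, seed = 1)
  expect_true(all(rk$frequency == 1))
  expect_equal(nrow(rk), nrow(dat) - 1)   # spanning: one parent per non-root gene
})

test_that("planted structure is recovered with high AUPR", {
  good <- 0
  for (s in 1:6) {
    truth <- cachedTruth(seed = s + 70, nRegulators = 9, nEnzymes = 5)
    dat <- generateExpressionDataset(truth, labConfig(seed = s, nRegulators = 9, nEnzymes = 5))
    rk <- ensembleRank(dat, prior = NULL, K = 100, seed = s,
                       candidates = regulators(truth))
    te <- dbnEdges(truth)
    te <- te[te$parent != te$child, ]   # self-persistence is not inferred
    if (auprEdges(rk, te) >= 0.8) good <- good + 1
  }
  expect_gte(good, 5)
})

test_that("prior edges survive at the frequency floor", {
  truth <- cachedTruth(seed = 5, nRegulators = 9, nEnzymes = 5)
  dat <- generateExpressionDataset(truth, labConfig(seed = 5, nRegulators = 9,
                                                    nEnzymes = 5, nExprPoints = 120))
  prior <- regulatoryDBN(rownames(dat),
                         ifelse(rownames(dat) %in% regulators(truth), "regulator", "enzyme"),
                         data.frame(parent = "MIG1", child = "ENZ05", weight = 0.5))
  rk <- ensembleRank(dat, prior = prior, K = 30, seed = 2, wMin = 0)
  row <- rk[rk$parent == "MIG1" & rk$child == "ENZ05", ]
  expect_equal(nrow(row), 1)
  expect_gte(row$frequency, 0.5)
})

test_that("ensemble frequencies are equivariant to gene relabeling", {
  truth <- cachedTruth(seed = 5, nRegulators = 9, nEnzymes = 5)
  dat <- generateExpressionDataset(truth, labConfig(seed = 5, nRegulators = 9,
                                                    nEnzymes = 5, nExprPoints = 100))
  rk1 <- ensembleRank(dat, prior = NULL, K = 25, seed = 3,
                      candidates = regulators(truth), wMin = 0)
  # bijective rename that preserves sort order, so sampling draws align
  ren <- setNames(paste0(rownames(dat), "x"), rownames(dat))
  dat2 <- dat
  rownames(dat2) <- unname(ren[rownames(dat)])
  rk2 <- ensembleRank(dat2, prior = NULL, K = 25, seed = 3,
                      candidates = unname(ren[regulators(truth)]), wMin = 0)
  key1 <- paste(ren[rk1$parent], ren[rk1$child])
  expect_setequal(paste(rk2$parent, rk2$child), key1)
  m <- match(paste(rk2$parent, rk2$child), key1)
  expect_equal(rk2$frequency, rk1$frequency[m])
})

test_that("forward selection accepts planted edges and ignores noise edges", {
  acceptedPlanted <- 0
  nullAccepts <- 0
  for (s in 1:8) {
    base <- regulatoryDBN(c("A", "B", "C"), rep("regulator", 3),
                          data.frame(parent = "A", child = "B", weight = 0.7),
                          bias = c(A = 0.3, B = 0.1, C = 0.1), sigma = 0.1)
    full <- base
    full@edges <- rbind(full@edges, data.frame(parent = "B", child = "C", weight = 0.8))
    dat <- sampleDBNData(full, 200, seed = 400 + s)
    rank1 <- data.frame(parent = "B", child = "C", frequency = 1, weight = NA)
    sel <- forwardSelect(base, rank1, dat)
    if (nrow(attr(sel, "accepted"))) acceptedPlanted <- acceptedPlanted + 1
    # pure-noise candidate into an unrelated child
    datN <- sampleDBNData(base, 200, seed = 900 + s)
    rank0 <- data.frame(parent = "C", child = "A", frequency = 1, weight = NA)
    sel0 <- forwardSelect(base, rank0, datN)
    nullAccepts <- nullAccepts + nrow(attr(sel0, "accepted"))
  }
  expect_gte(acceptedPlanted, 7)
  expect_lte(nullAccepts, 1)
})

test_that("forward selection returns the base when the ranking is empty", {
  base <- randomStableDBN(4, 4, seed = 2)
  dat <- sampleDBNData(base, 30, seed = 1)
  rk <- data.frame(parent = character(0), child = character(0),
                   frequency = numeric(0), weight = numeric(0))
  out <- forwardSelect(base, rk, dat)
  expect_equal(out@edges[c("parent", "child")], base@edges[c("parent", "child")])
  expect_equal(nrow(attr(out, "accepted")), 0)
})
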