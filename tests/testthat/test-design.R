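# Experiment selection: KL machinery, active learning, coregulation mining,
# discriminative design.

test_that("gaussian KL matches its closed form and numerical integration", {
  expect_equal(gaussianKL(0, 1, 0, 1), 0)
  expect_equal(gaussianKL(0, 1, 1, 1), 0.5)
  expect_equal(gaussianKL(0, 1, 0, 2), log(2) - 3 / 8)
  expect_error(gaussianKL(0, 0, 0, 1), "positive")
  set.seed(2)
  for (i in 1:20) {
    mu1 <- rnorm(1); mu2 <- rnorm(1)
    sd1 <- runif(1, 0.3, 2); sd2 <- runif(1, 0.3, 2)
    f <- function(x) {
      p <- dnorm(x, mu1, sd1)
      ifelse(p > 0, p * (dnorm(x, mu1, sd1, log = TRUE) - dnorm(x, mu2, sd2, log = TRUE)), 0)
    }
    num <- integrate(f, mu1 - 12 * sd1, mu1 + 12 * sd1, rel.tol = 1e-10)$value
    expect_equal(gaussianKL(mu1, sd1, mu2, sd2), num, tolerance = 1e-6)
  }
})

test_that("self-generated evidence yields zero divergence for every gene", {
  for (s in c(1, 2)) {
    truth <- cachedTruth(seed = s)
    wt <- growthParams(simulateStrain(truth))
    rk <- adactiveRank(truth, wt)
    expect_lt(max(rk$divergence), 1e-6)
    # ranking ties break lexicographically
    expect_equal(rk$gene, sort(rk$gene))
  }
})

test_that("a planted discrepancy sends the defect path to the top", {
  hits <- 0
  for (s in 1:8) {
    truth <- cachedTruth(seed = s + 40)
    wt <- growthParams(simulateStrain(truth))
    pl <- plantSpuriousEdges(truth, n = 1, seed = s)
    rk <- adactiveRank(pl$model, wt)
    if (match(pl$planted$parent, rk$gene) <= 3) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("top-k selection honours k over large candidate sets", {
  truth <- cachedTruth(seed = 44, nRegulators = 40, nEnzymes = 12)
  wt <- growthParams(simulateStrain(truth))
  rk <- adactiveRank(truth, wt)
  expect_gte(nrow(rk), 40)
  expect_length(head(rk$gene, 40), 40)
  expect_length(randomDesign(rk$gene, 40, seed = 1), 40)
})

test_that("influence profiles: construction, antisymmetry, classification", {
  t <- 20
  act <- rbind(T1 = c(rep(1, 10), rep(0, 10)), T2 = c(rep(0.9, 10), rep(0.1, 10)))
  rep_ <- rbind(T3 = c(rep(0, 10), rep(1, 10)))
  dat <- rbind(act, rep_) + matrix(rnorm(60, 0, 0.01), 3)
  targets <- list(R1 = list(activated = c("T1", "T2"), repressed = "T3"),
                  R2 = list(activated = "T3", repressed = c("T1", "T2")))
  prof <- influenceProfiles(dat, targets)
  expect_equal(prof$class[prof$regulator == "R1"], "active->inactive")
  expect_equal(prof$class[prof$regulator == "R2"], "inactive->active")
  infl <- attr(prof, "influence")
  expect_equal(infl["R1", ], -infl["R2", ], tolerance = 1e-12)
  # regulator with no expressed targets: zero profile plus warning
  expect_warning(
    p2 <- influenceProfiles(dat, c(targets, list(R3 = list(activated = "NOPE",
                                                           repressed = character(0))))),
    "no expressed targets")
  expect_equal(p2$class[p2$regulator == "R3"], "stable")
})

test_that("coregmine finds border regulators of antagonistic dense subgraphs", {
  # two 3-cliques sharing targets internally, opposite classes, one bridge
  targets <- list(
    A1 = list(activated = c("x1", "x2", "x3"), repressed = character(0)),
    A2 = list(activated = c("x1", "x2", "x4"), repressed = character(0)),
    A3 = list(activated = c("x2", "x3", "x4"), repressed = character(0)),
    B1 = list(activated = c("y1", "y2", "y3"), repressed = character(0)),
    B2 = list(activated = c("y1", "y2", "y4"), repressed = character(0)),
    B3 = list(activated = c("y2", "y3", "y4", "x1", "x2"), repressed = character(0)))
  n <- 20
  mk <- function(hi) c(rep(1, 10), rep(0, 10)) * hi + c(rep(0, 10), rep(1, 10)) * (1 - hi)
  dat <- rbind(x1 = mk(1), x2 = mk(1), x3 = mk(1), x4 = mk(1),
               y1 = mk(0), y2 = mk(0), y3 = mk(0), y4 = mk(0))
  dat <- dat + matrix(rnorm(length(dat), 0, 0.01), nrow(dat))
  prof <- influenceProfiles(dat, targets)
  sel <- coregmineSelect(prof, targets, jMin = 0.3, dMin = 0.6)
  # the A-side node adjacent to the B clique is the bridge endpoint
  expect_true(length(sel) >= 1)
  expect_true(all(sel %in% c("A1", "A2", "A3")))
  expect_equal(sel[1], "A1")   # A1 shares x1, x2 with B3
  # all regulators in one class -> nothing antagonistic
  sameCls <- influenceProfiles(dat, targets[1:3])
  expect_length(coregmineSelect(sameCls, targets[1:3]), 0)
  # jMin = 1 on regulators with disjoint targets -> empty graph, empty list
  disj <- list(D1 = list(activated = "x1", repressed = character(0)),
               D2 = list(activated = "y1", repressed = character(0)))
  profD <- influenceProfiles(dat, disj)
  expect_length(coregmineSelect(profD, disj, jMin = 1), 0)
  expect_error(coregmineSelect(profD[1, , drop = FALSE], disj[1]), "at least 2")
})

test_that("coregmine selection is invariant to regulator relabeling", {
  targets <- list(
    A1 = list(activated = c("x1", "x2"), repressed = character(0)),
    A2 = list(activated = c("x1", "x2"), repressed = character(0)),
    B1 = list(activated = character(0), repressed = c("x1", "x2")))
  n <- 20
  dat <- rbind(x1 = c(rep(1, 10), rep(0, 10)), x2 = c(rep(1, 10), rep(0, 10)))
  dat <- dat + matrix(rnorm(length(dat), 0, 0.01), nrow(dat))
  sel1 <- coregmineSelect(influenceProfiles(dat, targets), targets)
  ren <- c(A1 = "Q9", A2 = "Q1", B1 = "Q5")
  targets2 <- setNames(targets, ren[names(targets)])
  sel2 <- coregmineSelect(influenceProfiles(dat, targets2), targets2)
  expect_setequal(unname(ren[sel1]), sel2)
})

test_that("adana: disagreement ranking and importance scoring", {
  truth <- cachedTruth(seed = 1)
  # identical models never disagree; selection is lexicographic
  d0 <- adanaDisagreement(truth, truth, regulators(truth), k = 3)
  expect_true(all(d0$disagreement == 0))
  expect_equal(d0$gene, sort(regulators(truth))[1:3])
  # a model lacking respiration gating disagrees most on shift-path deletions
  pl <- plantSpuriousEdges(truth, n = 1, seed = 2)
  dd <- adanaDisagreement(truth, pl$model, regulators(truth), k = 5)
  expect_true(pl$planted$revealer %in% dd$gene[1:2])
  expect_true(all(diff(dd$disagreement) <= 1e-12))
  # importance: the shift master regulator dominates; inert genes score ~0
  imp <- adanaImportance(truth, c("HAP4", "CAT8", "MIG1", "NRG1"))
  expect_true(imp$gene[1] %in% c("CAT8", "HAP4"))
  # a gene with no outgoing edges and no reaction rule scores ~ 0
  inertEnz <- setdiff(enzymes(truth), c("HXT1", "PDC1", "ADH2", "COX4"))
  if (length(inertEnz)) {
    impInert <- adanaImportance(truth, inertEnz[1])
    expect_lt(impInert$importance, 0.02)
  }
  # only strong edges count in the connectivity term
  e <- dbnEdges(truth)
  strongOut <- sum(abs(e$weight[e$parent == "HAP4" & abs(e$weight) > 0.3]))
  impH <- adanaImportance(truth, "HAP4")
  base <- abs(growthParams(simulateStrain(truth))@postRate -
              growthParams(simulateStrain(applyKnockout(truth, "HAP4")))@postRate)
  expect_equal(impH$importance, base + 0.1 * strongOut, tolerance = 1e-8)
})

test_that("random design is seeded, sized, and bounded by the pool", {
  pool <- sprintf("G%02d", 1:30)
  expect_identical(randomDesign(pool, 10, seed = 5), randomDesign(pool, 10, seed = 5))
  expect_false(identical(randomDesign(pool, 10, seed = 5), randomDesign(pool, 10, seed = 6)))
  expect_setequal(randomDesign(pool, 30, seed = 1), pool)
  expect_error(randomDesign(pool, 31, seed = 1), "exceeds")
})
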