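# Forward propagation, parameter fitting, leave-one-out error.

test_that("forward step follows the linear-Gaussian propagation formula", {
  dbn <- regulatoryDBN(
    c("P1", "P2", "C", "L"), rep("regulator", 4),
    data.frame(parent = c("P1", "P2"), child = c("C", "C"), weight = c(2, -1)),
    bias = c(P1 = 0, P2 = 0, C = 0.05, L = 0.2),
    sigma = c(P1 = 0, P2 = 0, C = 0.05, L = 0.1))
  s <- geneStateSlice(c(P1 = 0.4, P2 = 0.1, C = 0, L = 9),
                      c(P1 = 0.1, P2 = 0.2, C = 0, L = 9))
  nxt <- forwardStep(dbn, s)
  # hand evaluation: mean 2*0.4 - 1*0.1 + 0.05; var 4*0.01 + 1*0.04 + 0.0025
  expect_equal(nxt$mean[["C"]], 0.75)
  expect_equal(nxt$sd[["C"]], sqrt(4 * 0.01 + 1 * 0.04 + 0.0025))
  # parentless node is forced to its bias regardless of input
  expect_equal(nxt$mean[["L"]], 0.2)
  expect_equal(nxt$sd[["L"]], 0.1)
  expect_error(forwardStep(dbn, geneStateSlice(c(P1 = 1), c(P1 = 0))), "missing|cover")
})

test_that("clamped genes stay at (0,0) through forward steps", {
  dbn <- randomStableDBN(5, 6, seed = 3)
  tr <- forwardSimulate(dbn, n = 10, knockouts = "G02")
  expect_true(all(stateMeans(tr)["G02", -1] == 0))
  expect_true(all(stateSds(tr)["G02", -1] == 0))
})

test_that("noise-free zero-weight network settles to its biases", {
  dbn <- regulatoryDBN(c("A", "B"), c("regulator", "regulator"), NULL,
                       bias = c(A = 0.3, B = 0.7), sigma = 0,
                       initMean = c(A = 1, B = 0), initSd = 0)
  tr <- forwardSimulate(dbn, n = 3)
  expect_equal(unname(stateMeans(tr)[, 2]), c(0.3, 0.7))
  expect_equal(unname(stateMeans(tr)[, 4]), c(0.3, 0.7))
})

test_that("stable linear systems converge to the fixed point of x = b + Wx", {
  for (s in 1:5) {
    dbn <- randomStableDBN(6, 8, seed = s, sigma = 0)
    tr <- forwardSimulate(dbn, n = 200)
    g <- dbn@nodes
    W <- matrix(0, 6, 6, dimnames = list(g, g))
    e <- dbn@edges
    W[cbind(match(e$child, g), match(e$parent, g))] <- e$weight
    fix <- solve(diag(6) - W, dbn@bias[g])
    expect_lt(max(abs(stateMeans(tr)[, 201] - fix)), 1e-6)
  }
})

test_that("forward variance is monotone in every node's sigma", {
  base <- randomStableDBN(5, 6, seed = 11, sigma = 0.05)
  tr0 <- forwardSimulate(base, n = 20)
  for (g in base@nodes) {
    up <- base
    up@sigma[[g]] <- up@sigma[[g]] * 2
    tr1 <- forwardSimulate(up, n = 20)
    expect_true(all(stateSds(tr1) >= stateSds(tr0) - 1e-12), info = g)
  }
})

test_that("noise-free data is interpolated exactly at ridge 0", {
  dbn <- randomStableDBN(5, 7, seed = 2, sigma = 0)
  dat <- sampleDBNData(dbn, 40, seed = 1)
  fit <- fitParameters(dbn, dat, ridge = 0)
  m <- merge(dbn@edges, fit@edges, by = c("parent", "child"))
  expect_lt(max(abs(m$weight.x - m$weight.y)), 1e-8)
  expect_lt(max(abs(fit@bias - dbn@bias[names(fit@bias)])), 1e-8)
})

test_that("infinite ridge shrinks weights to zero and bias to the child mean", {
  dbn <- randomStableDBN(4, 5, seed = 5, sigma = 0.1)
  dat <- sampleDBNData(dbn, 60, seed = 2)
  fit <- fitParameters(dbn, dat, ridge = 1e12)
  expect_lt(max(abs(fit@edges$weight)), 1e-6)
  for (ch in unique(dbn@edges$child)) {
    expect_equal(fit@bias[[ch]], mean(dat[ch, -1]), tolerance = 1e-6)
  }
})

test_that("ridge fitting recovers planted weights from noisy data", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    truth <- randomPersistentDBN(nGenes = 10, seed = s + 30, sigma = 0.1)
    dat <- sampleTrajectory(truth, 501, seed = s)
    fit <- fitParameters(truth, dat, ridge = 1e-2)
    m <- merge(truth@edges, fit@edges, by = c("parent", "child"))
    hits <- hits + sum(abs(m$weight.x - m$weight.y) < 0.05)
    total <- total + nrow(m)
  }
  expect_gte(hits / total, 0.95)
})

test_that("fitting is equivariant to gene relabeling", {
  dbn <- randomStableDBN(5, 6, seed = 8, sigma = 0.1)
  dat <- sampleDBNData(dbn, 50, seed = 3)
  fit1 <- fitParameters(dbn, dat, ridge = 1e-2)
  perm <- rev(dbn@nodes)
  relab <- setNames(sprintf("X%02d", seq_along(perm)), perm)
  dbn2 <- regulatoryDBN(unname(relab[dbn@nodes]), rep("regulator", 5),
                        data.frame(parent = relab[dbn@edges$parent],
                                   child = relab[dbn@edges$child],
                                   weight = dbn@edges$weight),
                        bias = setNames(dbn@bias, relab[names(dbn@bias)]),
                        sigma = setNames(dbn@sigma, relab[names(dbn@sigma)]),
                        initMean = setNames(dbn@initMean, relab[names(dbn@initMean)]),
                        initSd = setNames(dbn@initSd, relab[names(dbn@initSd)]))
  dat2 <- dat
  rownames(dat2) <- unname(relab[rownames(dat)])
  fit2 <- fitParameters(dbn2, dat2, ridge = 1e-2)
  expect_equal(unname(fit2@bias[relab[dbn@nodes]]), unname(fit1@bias[dbn@nodes]))
  m <- merge(transform(fit1@edges, parent = relab[parent], child = relab[child]),
             fit2@edges, by = c("parent", "child"))
  expect_equal(m$weight.x, m$weight.y, tolerance = 1e-10)
})

test_that("singularity is reported when transitions < parameters at ridge 0", {
  dbn <- regulatoryDBN(c("A", "B", "C", "D"), rep("regulator", 4),
                       data.frame(parent = c("A", "B", "C"),
                                  child = c("D", "D", "D"), weight = 0))
  dat <- matrix(rnorm(12), 4, 3, dimnames = list(c("A", "B", "C", "D"), 1:3))
  expect_error(fitParameters(dbn, dat, ridge = 0), "singular")
})

test_that("the hat-matrix LOO error equals explicit per-fold refitting", {
  dbn <- randomStableDBN(4, 5, seed = 13, sigma = 0.1)
  dat <- sampleDBNData(dbn, 12, seed = 4)
  fast <- looPredictionError(dbn, dat, ridge = 1e-2)
  # explicit refit oracle
  g <- dbn@nodes
  nT <- ncol(dat) - 1L
  tot <- 0
  for (child in g) {
    pa <- dbn@edges$parent[dbn@edges$child == child]
    errs <- numeric(nT)
    for (f in seq_len(nT)) {
      tr <- setdiff(seq_len(nT), f)
      X <- cbind(1, t(dat[pa, tr, drop = FALSE]))
      y <- dat[child, tr + 1L]
      pen <- diag(c(0, rep(1e-2, length(pa))), length(pa) + 1L)
      beta <- solve(crossprod(X) + pen, crossprod(X, y))
      xf <- c(1, dat[pa, f])
      errs[f] <- (dat[child, f + 1L] - sum(xf * beta))^2
    }
    tot <- tot + mean(errs)
  }
  expect_equal(fast, tot / length(g), tolerance = 1e-10)
})

test_that("LOO error reflects structure: zero on noise-free data, helped by true parents", {
  # noise-free data with persistent excitation (a linear oscillator, so the
  # design matrix stays full rank in every fold) is predicted exactly
  th <- 1.0
  osc <- regulatoryDBN(c("O1", "O2"), rep("regulator", 2),
                       data.frame(parent = c("O1", "O2", "O1", "O2"),
                                  child = c("O1", "O1", "O2", "O2"),
                                  weight = c(cos(th), -sin(th), sin(th), cos(th))),
                       bias = 0, sigma = 0,
                       initMean = c(O1 = 0.8, O2 = 0.2), initSd = 0)
  dat <- sampleDBNData(osc, 12, seed = 1)
  expect_lt(looPredictionError(osc, dat, ridge = 0), 1e-12)
  # adding a truly predictive parent lowers LOO error (majority over seeds)
  wins <- 0
  for (s in 1:10) {
    nodes <- c("P", "C")
    full <- regulatoryDBN(nodes, rep("regulator", 2),
                          data.frame(parent = "P", child = "C", weight = 0.8),
                          bias = c(P = 0.2, C = 0.1), sigma = 0.1)
    dat2 <- sampleDBNData(full, 40, seed = 100 + s)
    empty <- regulatoryDBN(nodes, rep("regulator", 2), NULL,
                           bias = c(P = 0.2, C = 0.1), sigma = 0.1)
    if (looPredictionError(full, dat2) < looPredictionError(empty, dat2)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("expression TSV round-trips with time stamps", {
  m <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), c(0, 0.5, 1, 1.5)))
  f <- tempfile(fileext = ".tsv")
  writeExpressionTSV(m, f)
  m2 <- readExpressionTSV(f)
  expect_equal(unname(m2[,]), unname(m), tolerance = 1e-12)
  expect_equal(attr(m2, "times"), c(0, 0.5, 1, 1.5))
})
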