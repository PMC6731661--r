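# Curve preprocessing, growth-parameter extraction, model comparison stats.

mkReps <- function(t, od, reps = 8, noise = 0, seed = 1, glucose = NULL) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(reps), function(r) {
    df <- data.frame(replicate = r, time_h = t,
                     od560 = od + rnorm(length(t), 0, noise))
    if (!is.null(glucose)) df$glucose_mM <- glucose
    df
  }))
}

test_that("preprocessing: blank, clipping, smoothing, averaging", {
  t <- seq(0, 10, 0.5)
  od <- 0.05 * exp(0.3 * t)
  # a single clean replicate passes through unchanged
  one <- suppressWarnings(preprocessCurve(mkReps(t, od, reps = 1)))
  expect_equal(one$od560, as.numeric(stats::runmed(od, 5)), tolerance = 1e-12)
  # eight identical replicates average to each
  expect_warning(preprocessCurve(mkReps(t, od, reps = 3)), "replicate")
  eight <- preprocessCurve(mkReps(t, od, reps = 8))
  expect_equal(eight$od560, as.numeric(stats::runmed(od, 5)))
  # an isolated +1 OD spike is removed by the median window
  spiked <- od; spiked[10] <- spiked[10] + 1
  sm <- suppressWarnings(preprocessCurve(mkReps(t, spiked, reps = 1)))
  expect_lt(max(abs(sm$od560 - stats::runmed(od, 5))), 0.05)
  expect_lt(max(abs(sm$od560 - od)[8:12]), 0.06)   # spike region repaired
  # blank subtraction and clipping at zero
  bl <- suppressWarnings(preprocessCurve(mkReps(t, od, reps = 1), blank = 0.1))
  expect_true(all(bl$od560 >= 0))
  # replicate order does not matter
  raw <- mkReps(t, od, reps = 8, noise = 0.01)
  shuf <- raw[rev(seq_len(nrow(raw))), ]
  expect_equal(preprocessCurve(raw)$od560, preprocessCurve(shuf)$od560)
  expect_error(preprocessCurve(raw[0, ]), "no readings")
})

test_that("pure exponential: rate recovered, no shift declared", {
  t <- seq(0, 12, 0.5)
  gp <- growthParameters(data.frame(time_h = t, od560 = 0.05 * exp(0.4 * t)))
  expect_equal(gp@preRate, 0.4, tolerance = 1e-6)
  expect_false(gp@shiftDetected)
  # with glucose never depleted the same holds
  gp2 <- growthParameters(data.frame(time_h = t, od560 = 0.05 * exp(0.4 * t),
                                     glucose_mM = 50 - t))
  expect_equal(gp2@preRate, 0.4, tolerance = 1e-6)
  expect_false(gp2@shiftDetected)
})

test_that("biphasic curves: breakpoint, segment rates, glucose priority", {
  t <- seq(0, 30, 0.5)
  od <- ifelse(t <= 10, 0.05 * exp(0.4 * t), 0.05 * exp(0.4 * 10) * exp(0.1 * (t - 10)))
  glc <- pmax(20 - 2.05 * t, 0)   # crosses 0.1 mM just before 10 h
  gp <- growthParameters(data.frame(time_h = t, od560 = od, glucose_mM = glc))
  expect_true(gp@shiftDetected)
  expect_lt(abs(gp@shiftTime - 10), 0.51)
  expect_equal(gp@preRate, 0.4, tolerance = 0.01)
  expect_equal(gp@postRate, 0.1, tolerance = 0.01)
  # same curve without glucose: the log-OD breakpoint fit finds the shift
  gp2 <- growthParameters(data.frame(time_h = t, od560 = od))
  expect_true(gp2@shiftDetected)
  expect_lt(abs(gp2@shiftTime - 10), 1.01)
  expect_equal(gp2@postRate, 0.1, tolerance = 0.01)
})

test_that("flat and degenerate curves give zero rates and full-window lag", {
  t <- seq(0, 10, 0.5)
  gp <- growthParameters(data.frame(time_h = t, od560 = rep(0.2, length(t))))
  expect_equal(gp@preRate, 0)
  expect_equal(gp@postRate, 0)
  expect_false(gp@shiftDetected)
  expect_equal(gp@lag, 10)
  expect_error(growthParameters(data.frame(time_h = c(0, 1, 1, 2, 3, 4),
                                           od560 = rep(1, 6))), "increasing")
  expect_error(growthParameters(data.frame(time_h = 0:4, od560 = rep(1, 5))),
               "6 time points")
})

test_that("lag and yield are read off the curve", {
  t <- seq(0, 20, 0.5)
  od <- pmin(0.1 * exp(0.3 * pmax(t - 4, 0)), 1.4)   # 4 h lag, plateau 1.4
  gp <- growthParameters(data.frame(time_h = t, od560 = od))
  expect_equal(gp@lag, 4.5, tolerance = 0.51)
  expect_equal(gp@yieldOD, 1.4, tolerance = 1e-6)
})

test_that("virtual-lab curves at zero noise recover the generating rates", {
  ok <- 0
  for (s in 1:10) {
    truth <- cachedTruth(seed = s + 60, nRegulators = 9, nEnzymes = 5)
    sim <- simulateStrain(truth)
    gp <- growthParams(sim)
    fx <- sim@fluxes["BIOMASS", ]
    tt <- sliceTimes(sim)[-1]
    # realized growth rates inside each phase (away from the transition)
    muPre <- stats::median(fx[tt <= gp@shiftTime - 1 & tt >= 1])
    muPost <- stats::median(fx[tt >= gp@shiftTime + 2 & fx > 0.01])
    ok <- ok + (abs(gp@preRate - muPre) < 0.01) + (abs(gp@postRate - muPost) < 0.01)
  }
  expect_gte(ok, 18)   # 2 checks x 10 seeds, allow one marginal case
})

test_that("compareModels: ratio and exact signed-rank p-value", {
  set.seed(1)
  a <- runif(10, 0.1, 1)
  expect_equal(compareModels(a, a), list(ratio = 0, p = 1, n = 0L))
  # halving every error: ratio 0.5, exact p = 2 * 2^-10
  cmp <- compareModels(a, a / 2)
  expect_equal(cmp$ratio, 0.5)
  expect_equal(cmp$p, 2 / 2^10, tolerance = 1e-12)
  expect_error(compareModels(a, a[1:5]), "paired")
  expect_error(compareModels(a[1:3], a[1:3]), "at least 5")
})

test_that("exact p-values match full sign-flip enumeration for n <= 12", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    a <- runif(n, 0.2, 1)
    b <- pmax(a + rnorm(n, -0.05, 0.15), 0.01)
    d <- a - b
    d <- d[d != 0]
    cmp <- compareModels(a, b)
    # enumerate all 2^n sign assignments of the ranked |d|
    r <- rank(abs(d))
    Wobs <- sum(r[d > 0])
    total <- 0; extreme <- 0
    for (mask in 0:(2^length(d) - 1)) {
      signs <- as.integer(intToBits(mask))[seq_along(d)]
      W <- sum(r[signs == 1])
      total <- total + 1
      # two-sided: as or more extreme in either tail
      EW <- length(d) * (length(d) + 1) / 4
      if (abs(W - EW) >= abs(Wobs - EW) - 1e-9) extreme <- extreme + 1
    }
    expect_equal(cmp$p, extreme / total, tolerance = 1e-10, info = paste("n =", n))
  }
})

test_that("breaking the pairing weakens the comparison", {
  worse <- 0
  for (s in 1:50) {
    set.seed(s)
    a <- runif(12, 0.2, 1)
    b <- a * runif(12, 0.4, 0.8)   # consistently better, paired
    pPaired <- compareModels(a, b)$p
    pBroken <- compareModels(a, sample(b))$p
    if (pBroken >= pPaired) worse <- worse + 1
  }
  expect_gte(worse, 45)
})
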