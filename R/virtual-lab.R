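#' @include simulate.R phenotype.R
NULL

#' Configuration of the virtual laboratory
#'
#' Bundles the knobs of the in-silico lab that stands in for a robotised
#' culture facility: model size, observation noise, replication, and the
#' sampling grid. Growth experiments run a 45 h batch culture sampled every
#' \code{dt} hours with \code{replicates} plate replicates (the defaults
#' mirror common automated diauxic-shift protocols: 45 h OD560 courses, at
#' least eight replicates per strain). Expression time courses are sampled on
#' the same slice grid for \code{nExprPoints} slices.
#'
#' \code{nRegulators}/\code{nEnzymes} are total node counts; the generator
#' always includes its fixed diauxic core (8 regulators, 4 enzymes), so
#' values below the core size are rounded up to it.
#'
#' @param nRegulators,nEnzymes total node counts (floored at the core sizes).
#' @param extraEdgesPerNode mean number of incoming random edges per
#'   non-core node.
#' @param sigmaRange range for random process-noise SDs of non-core nodes.
#' @param odNoise,glucoseNoise,exprNoise observation noise SDs (OD units,
#'   mM, activity units).
#' @param replicates plate replicates per growth experiment.
#' @param horizon,dt culture duration and sampling interval (h).
#' @param nExprPoints slices in a generated expression time course.
#' @param odFactor OD560 units per gDW/L.
#' @param glucose0 starting glucose (mM).
#' @param seed RNG seed; mandatory for any stochastic use.
#' @return a \code{labConfig} list.
#' @export
labConfig <- function(nRegulators = 10, nEnzymes = 6, extraEdgesPerNode = 1,
                      sigmaRange = c(0.05, 0.1), odNoise = 0.01,
                      glucoseNoise = 0.05, exprNoise = 0.02, replicates = 8,
                      horizon = 45, dt = 0.5, nExprPoints = 300,
                      odFactor = 1, glucose0 = 20, seed = 1) {
  stopifnot(nRegulators >= 1, nEnzymes >= 1, odNoise >= 0, glucoseNoise >= 0,
            exprNoise >= 0, replicates >= 1, horizon > 0, dt > 0)
  structure(list(
    nRegulators = max(nRegulators, 8L), nEnzymes = max(nEnzymes, 4L),
    extraEdgesPerNode = extraEdgesPerNode, sigmaRange = sigmaRange,
    odNoise = odNoise, glucoseNoise = glucoseNoise, exprNoise = exprNoise,
    replicates = replicates, horizon = horizon, dt = dt,
    nExprPoints = nExprPoints, odFactor = odFactor, glucose0 = glucose0,
    seed = seed), class = "labConfig")
}

# The fixed diauxic core shared by every ground truth: a fermentation branch
# (glucose import + pyruvate-decarboxylase step), a respiration branch
# (ethanol import + oxidative step) activated by the CAT8 -> HAP4 cascade,
# glucose signalling through MIG1, and three repressor->activator pairs
# (MIG1 -| SIP4, NRG1 -| ADR1, RGT1 -| STD1) that keep three regulators
# near-silent in the wild type but de-repressed in the repressor deletants.
coreRegulators <- c("MIG1", "CAT8", "SIP4", "NRG1", "ADR1", "RGT1", "STD1", "HAP4")
coreEnzymes <- c("HXT1", "PDC1", "ADH2", "COX4")

coreMetabolicModel <- function() {
  mets <- data.frame(
    id = c("glc_e", "eth_e", "o2_e", "co2_e", "glc_i", "eth_i", "X_c"),
    external = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    buffered = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    carbon = c(6, 2, 0, 1, 6, 2, 12),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("GLCupt", "FERM", "ETHupt", "RESP", "BIOMASS",
           "EX_glc", "EX_eth", "EX_o2", "EX_co2"),
    lb = c(0, 0, 0, 0, 0, -10, -3.2, -8, 0),
    ub = c(10, 10, 3.2, 3.2, 10, 0, 100, 0, 100),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- list(
    c(glc_e = -1, glc_i = 1),
    c(glc_i = -1, eth_e = 1.6, co2_e = 1.6, X_c = 0.1),
    c(eth_e = -1, eth_i = 1),
    c(eth_i = -1, o2_e = -2, co2_e = 0.8, X_c = 0.1),
    c(X_c = -1 / 0.35),
    c(glc_e = -1), c(eth_e = -1), c(o2_e = -1), c(co2_e = -1))
  kin <- data.frame(
    metabolite = c("glc_e", "eth_e"),
    exchange = c("EX_glc", "EX_eth"),
    vmax = c(10, 3), km = c(0.5, 1),
    stringsAsFactors = FALSE)
  metabolicModel(
    mets, rx, biomassId = "BIOMASS",
    exchangeIds = c("EX_glc", "EX_eth", "EX_o2", "EX_co2"),
    geneRules = list(GLCupt = "HXT1", FERM = "PDC1",
                     ETHupt = "ADH2", RESP = "COX4"),
    uptakeKinetics = kin)
}

#' Generate a ground-truth hybrid model
#'
#' Builds a toy diauxic-shift model: a fermentation route (fast, low biomass
#' yield per carbon) and a respiration route (slow, high yield) in the
#' metabolic layer, a glucose-repression/derepression cascade in the
#' regulatory layer (MIG1 active on glucose; CAT8 -- set by the
#' metabolite-to-gene rules once glucose runs low -- driving HAP4, which
#' activates the respiratory enzymes), plus randomly wired additional
#' regulators and enzymes up to the configured counts. Two metabolite rules
#' implement the shift switch: glucose < 0.75 mM sets CAT8 to (1, 0.05),
#' glucose >= 0.75 mM sets it to (0, 0.02). The generated wild type is
#' simulated and the model is only returned if it exhibits a diauxic shift
#' (shift detected, glucose depleted at the shift, pre-shift faster than
#' post-shift growth); otherwise a reseeded attempt is made.
#'
#' @param config a [labConfig()].
#' @param maxRetries attempts before giving up.
#' @return a validated [HybridModel-class] (deterministic per seed).
#' @export
generateGroundTruth <- function(config = labConfig(), maxRetries = 10) {
  for (attempt in seq_len(maxRetries)) {
    model <- withSeed(subSeed(config$seed, attempt - 1L),
                      buildGroundTruth(config))
    sim <- simulateStrain(model, horizon = config$horizon, dt = config$dt,
                          culture = initialCulture(model, glucose = config$glucose0),
                          odFactor = config$odFactor)
    gp <- growthParams(sim)
    glc <- cultureSeries(sim)$glc_e
    depleted <- any(glc < 0.1)
    if (gp@shiftDetected && depleted && !is.na(gp@shiftTime) &&
        gp@preRate > gp@postRate && gp@postRate > 0.01) {
      return(model)
    }
  }
  stop("could not generate a model passing the diauxic check in ",
       maxRetries, " attempts")
}

buildGroundTruth <- function(config) {
  nR <- config$nRegulators
  nE <- config$nEnzymes
  extraR <- if (nR > 8) sprintf("REG%02d", 9:nR) else character(0)
  extraE <- if (nE > 4) sprintf("ENZ%02d", 5:nE) else character(0)
  regs <- c(coreRegulators, extraR)
  enz <- c(coreEnzymes, extraE)
  nodes <- c(regs, enz)
  types <- c(rep("regulator", length(regs)), rep("enzyme", length(enz)))

  # source regulators carry an autoregressive self-edge (protein persistence
  # over one slice); their bias is scaled so the stationary mean is unchanged
  selfW <- 0.85
  mean0 <- c(MIG1 = 0.9, NRG1 = 0.88, RGT1 = 0.86)
  bias <- c(mean0 * (1 - selfW), CAT8 = 0, SIP4 = 0.85, ADR1 = 0.82,
            STD1 = 0.8, HAP4 = 0,
            HXT1 = 0.95, PDC1 = 0.92, ADH2 = 0.05, COX4 = 0.02)
  sigma <- setNames(rep(0.05, length(bias)), names(bias))
  sigma[c("HXT1", "PDC1")] <- 0.04
  init <- c(MIG1 = 0.9, CAT8 = 0, SIP4 = 0.22, NRG1 = 0.88, ADR1 = 0.2,
            RGT1 = 0.86, STD1 = 0.21, HAP4 = 0,
            HXT1 = 0.95, PDC1 = 0.92, ADH2 = 0, COX4 = 0.02)
  edges <- data.frame(
    parent = c(names(mean0), "MIG1", "NRG1", "RGT1", "CAT8", "HAP4", "HAP4", "MIG1"),
    child = c(names(mean0), "SIP4", "ADR1", "STD1", "HAP4", "ADH2", "COX4", "ADH2"),
    weight = c(rep(selfW, 3), -0.7, -0.7, -0.68, 0.95, 1.0, 1.0, -0.1),
    stringsAsFactors = FALSE)

  extra <- c(extraR, extraE)
  for (gn in extra) {
    bias[gn] <- runif(1, 0.15, 0.85)
    sigma[gn] <- runif(1, config$sigmaRange[1], config$sigmaRange[2])
    init[gn] <- bias[gn]
  }
  for (gn in extraR) {   # persistent extra regulators
    edges <- rbind(edges, data.frame(parent = gn, child = gn, weight = selfW))
  }
  # random cross wiring restricted to a DAG over the extra nodes (parents are
  # core regulators or earlier extras), so self-persistence cannot combine
  # with a feedback cycle into an unstable loop
  # at most one incoming cross edge per extra node (sparse peripheral
  # regulome; also keeps the per-child design well conditioned)
  nNew <- min(round(config$extraEdgesPerNode * length(extra)), length(extra))
  if (length(extra) && nNew > 0) {
    open <- base::sample(seq_along(extra), nNew)
    for (chIdx in open) {
      ch <- extra[chIdx]
      pPool <- c(coreRegulators, extraR[seq_len(min(chIdx - 1, length(extraR)))])
      pPool <- setdiff(pPool, ch)
      p <- base::sample(pPool, 1)
      w <- base::sample(c(-1, 1), 1) * runif(1, 0.15, 0.35)
      edges <- rbind(edges, data.frame(parent = p, child = ch, weight = w))
    }
  }
  # re-centre extra biases so each keeps its drawn stationary mean despite
  # self-persistence and incoming wiring (extras form a DAG, so the
  # steady-state means resolve in index order)
  meanSS <- c(mean0, CAT8 = 0, SIP4 = 0.22, ADR1 = 0.2, STD1 = 0.21, HAP4 = 0,
              HXT1 = 0.95, PDC1 = 0.92, ADH2 = 0, COX4 = 0.02)
  for (gn in extra) {
    target <- init[gn]
    inc <- edges[edges$child == gn & edges$parent != gn, , drop = FALSE]
    drive <- if (nrow(inc)) sum(inc$weight * meanSS[inc$parent]) else 0
    self <- if (gn %in% extraR) selfW else 0
    bias[gn] <- target * (1 - self) - drive
    meanSS[gn] <- target
  }
  dbn <- regulatoryDBN(nodes, types, edges, bias = bias[nodes],
                       sigma = sigma[nodes], initMean = init[nodes],
                       initSd = setNames(rep(0, length(nodes)), nodes))
  rules <- data.frame(
    metabolite = c("glc_e", "glc_e"),
    comparator = c("ge", "lt"),
    threshold = c(0.75, 0.75),
    target = c("CAT8", "CAT8"),
    mean = c(0, 1), sd = c(0.02, 0.05),
    stringsAsFactors = FALSE)
  hybridModel(dbn, coreMetabolicModel(), rules)
}

#' Random persistent regulatory network
#'
#' Generates a stable random DBN in which every gene carries an
#' autoregressive self-edge (protein persistence across one slice) and at
#' most one cross-regulatory parent, wired as a DAG so the system is
#' guaranteed stable. Stationary means are drawn in [0.2, 0.8] and the
#' biases solved to hit them. This is the planted ground truth used for
#' parameter-recovery studies: the self-edges give every regulator enough
#' stationary variance for its outgoing weights to be identifiable from a
#' finite time course.
#'
#' @param nGenes number of genes.
#' @param seed RNG seed.
#' @param sigma process-noise SD shared by all nodes.
#' @param selfWeight autoregressive coefficient (default 0.9).
#' @return a [RegulatoryDBN-class] (all nodes regulator-tagged).
#' @export
randomPersistentDBN <- function(nGenes = 10, seed = 1, sigma = 0.1,
                                selfWeight = 0.9) {
  stopifnot(nGenes >= 2, abs(selfWeight) < 1)
  withSeed(seed, {
    g <- sprintf("G%02d", seq_len(nGenes))
    means <- setNames(runif(nGenes, 0.2, 0.8), g)
    edges <- data.frame(parent = g, child = g, weight = selfWeight,
                        stringsAsFactors = FALSE)
    bias <- means * (1 - selfWeight)
    for (i in 2:nGenes) {
      p <- base::sample(g[seq_len(i - 1)], 1)
      w <- base::sample(c(-1, 1), 1) * runif(1, 0.15, 0.5)
      edges <- rbind(edges, data.frame(parent = p, child = g[i], weight = w))
      bias[g[i]] <- bias[g[i]] - w * means[p]
    }
    regulatoryDBN(g, rep("regulator", nGenes), edges, bias = bias,
                  sigma = sigma, initMean = means,
                  initSd = setNames(rep(sigma, nGenes), g))
  })
}

#' Plant spurious regulatory edges into a model
#'
#' Produces the "wrong" working model used to exercise refinement: edges are
#' added whose parent regulator is near-silent in the wild type because an
#' active repressor holds it down. Such a defect barely distorts wild-type
#' predictions but badly distorts the predicted phenotype of the repressor's
#' deletant (the "revealer" strain), which is exactly the situation a
#' growth-curve-driven revision loop can detect and undo.
#'
#' @param model a ground-truth [HybridModel-class].
#' @param n number of edges to plant (limited by eligible parents).
#' @param seed RNG seed.
#' @param wtMax maximum wild-type mean activity of an eligible parent.
#' @return list: \code{model} (with planted edges), \code{planted}
#'   (data.frame \code{parent}, \code{child}, \code{weight},
#'   \code{revealer}).
#' @export
plantSpuriousEdges <- function(model, n = 1, seed = 1, wtMax = 0.3) {
  sim <- simulateStrain(model)
  act <- rowMeans(stateMeans(sim))
  dbn <- regulatoryPart(model)
  e <- dbn@edges
  eligible <- character(0)
  revealer <- character(0)
  for (p in regulators(model)) {
    if (act[[p]] >= wtMax) next
    reps <- e$parent[e$child == p & e$weight < -0.4]
    reps <- reps[act[reps] > 0.5]
    if (length(reps)) {
      eligible <- c(eligible, p)
      revealer <- c(revealer, reps[1])
    }
  }
  if (!length(eligible)) stop("no eligible low-activity parents to plant from")
  childPool <- c("HAP4", "ADH2", "COX4")
  planted <- withSeed(seed, {
    k <- min(n, length(eligible))
    pick <- base::sample(seq_along(eligible), k)
    out <- NULL
    for (i in pick) {
      ch <- NULL
      for (cand in base::sample(childPool)) {
        if (cand != eligible[i] && !any(e$parent == eligible[i] & e$child == cand)) {
          ch <- cand
          break
        }
      }
      if (is.null(ch)) next
      out <- rbind(out, data.frame(
        parent = eligible[i], child = ch,
        weight = -(0.85 + 0.3 * runif(1)),
        revealer = revealer[i], stringsAsFactors = FALSE))
    }
    out
  })
  dbn@edges <- rbind(e, planted[c("parent", "child", "weight")])
  validObject(dbn)
  model@regulatory <- dbn
  list(model = model, planted = planted)
}

#' Run a virtual knockout experiment
#'
#' Simulates the ground-truth model with the requested deletions and emits
#' replicate OD560 and glucose curves with i.i.d. Gaussian observation noise
#' (floored at 0), the way a plate-reader experiment would report them.
#'
#' @param truth the ground-truth [HybridModel-class].
#' @param knockout gene ids to delete (empty for wild type).
#' @param config a [labConfig()]; \code{config$seed} drives the noise.
#' @return data.frame \code{strain}, \code{replicate}, \code{time_h},
#'   \code{od560}, \code{glucose_mM}.
#' @export
runVirtualExperiment <- function(truth, knockout = character(0),
                                 config = labConfig()) {
  sim <- simulateStrain(applyKnockout(truth, knockout),
                        horizon = config$horizon, dt = config$dt,
                        culture = initialCulture(truth, glucose = config$glucose0),
                        odFactor = config$odFactor)
  cs <- cultureSeries(sim)
  od <- cs$biomass * config$odFactor
  glc <- cs$glc_e
  strain <- if (length(knockout)) paste(knockout, collapse = "+") else "WT"
  withSeed(config$seed, {
    out <- do.call(rbind, lapply(seq_len(config$replicates), function(r) {
      data.frame(strain = strain, replicate = r, time_h = cs$time_h,
                 od560 = pmax(od + rnorm(length(od), 0, config$odNoise), 0),
                 glucose_mM = pmax(glc + rnorm(length(glc), 0, config$glucoseNoise), 0),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate an expression time course from a ground-truth model
#'
#' Samples one stochastic gene-state trajectory of the wild-type diauxic
#' simulation (process noise and rule SDs drawn per slice) over
#' \code{nExprPoints} slices, then adds i.i.d. Gaussian measurement noise --
#' a microarray-like genes x time-points matrix on the slice grid. The
#' course runs past culture saturation, so late samples carry
#' stationary-state fluctuations.
#'
#' @param truth the ground-truth [HybridModel-class].
#' @param config a [labConfig()].
#' @return numeric matrix genes x time points; column names and a
#'   \code{times} attribute hold the sampling times (h).
#' @export
generateExpressionDataset <- function(truth, config = labConfig()) {
  n <- config$nExprPoints
  horizon <- (n - 1) * config$dt
  sim <- simulateStrain(truth, horizon = horizon, dt = config$dt,
                        culture = initialCulture(truth, glucose = config$glucose0),
                        sample = TRUE, seed = subSeed(config$seed, 101L),
                        odFactor = config$odFactor)
  M <- stateMeans(sim)
  M <- withSeed(subSeed(config$seed, 102L),
                M + matrix(rnorm(length(M), 0, config$exprNoise), nrow(M)))
  colnames(M) <- format(sliceTimes(sim), trim = TRUE)
  attr(M, "times") <- sliceTimes(sim)
  M
}
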