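#' @include dfba.R dbn.R
NULL

#' Default culture conditions for the diauxic-shift setting
#'
#' Inoculum and medium used unless a model file or caller overrides them:
#' 0.05 gDW/L biomass in aerated low-glucose medium.
#'
#' @param model a [HybridModel-class] (supplies the medium metabolite set).
#' @param glucose,ethanol initial concentrations (mM).
#' @param biomass inoculum (gDW/L).
#' @return list with \code{biomass} and \code{conc}.
#' @export
initialCulture <- function(model, glucose = 20, ethanol = 0, biomass = 0.05) {
  met <- metabolicPart(model)@metabolites
  conc <- setNames(rep(0, sum(met$external)), met$id[met$external])
  if ("glc_e" %in% names(conc)) conc[["glc_e"]] <- glucose
  if ("eth_e" %in% names(conc)) conc[["eth_e"]] <- ethanol
  buf <- met$id[met$external & met$buffered]
  conc[buf[buf == "o2_e"]] <- 0.25
  list(biomass = biomass, conc = conc)
}

#' Simulate a strain with the coupled regulatory-metabolic loop
#'
#' Repeats, for each slice until the horizon: (1) a regulatory forward step
#' of the DBN; (2) a metabolic step -- gene states scale reaction bounds,
#' dynamic FBA advances biomass and medium; (3) regularisation -- every
#' metabolite rule whose comparator holds on the new culture state overwrites
#' its target gene's state for the next slice (on conflicting targets the
#' last rule in file order wins). Metabolite rules are also applied to the
#' initial slice from the initial medium. Knocked-out genes stay clamped at
#' (0, 0) throughout and zero out their reaction rules.
#'
#' By default state means and SDs are propagated (mean-field); with
#' \code{sample = TRUE} one stochastic trajectory is drawn (process noise and
#' rule SDs sampled, reproducible via \code{seed}).
#'
#' @param model a [HybridModel-class].
#' @param horizon total simulated time (h), > 0.
#' @param dt slice duration (h), > 0.
#' @param culture initial culture (default [initialCulture()]).
#' @param sample draw one stochastic gene-state trajectory instead of
#'   propagating means.
#' @param seed RNG seed for \code{sample = TRUE}.
#' @param odFactor OD560 units per gDW/L for the exported predicted curve.
#' @param pfba parsimonious-FBA tie-break in each metabolic step.
#' @return a [SimulationResult-class].
#' @examples
#' \dontrun{
#' res <- simulateStrain(applyKnockout(model, "HAP4"), horizon = 45, dt = 0.5)
#' growthParams(res)
#' }
#' @export
simulateStrain <- function(model, horizon = 45, dt = 0.5, culture = NULL,
                           sample = FALSE, seed = NULL, odFactor = 1,
                           pfba = TRUE) {
  stopifnot(horizon > 0, dt > 0)
  dbn <- regulatoryPart(model)
  met <- metabolicPart(model)
  ko <- knockouts(model)
  rules <- metaboliteRules(model)
  n <- max(1L, round(horizon / dt))
  g <- dbn@nodes
  G <- length(g)
  if (is.null(culture)) culture <- initialCulture(model)

  mats <- dbnMatrices(dbn)
  koIdx <- match(ko, g)
  M <- matrix(NA_real_, G, n + 1L, dimnames = list(g, paste0("t", 0:n)))
  Sd <- M
  RA <- matrix(FALSE, G, n + 1L, dimnames = dimnames(M))
  fluxes <- matrix(NA_real_, nrow(met@reactions), n,
                   dimnames = list(met@reactions$id, NULL))
  Xv <- rep(NA_real_, n + 1L)
  concM <- matrix(NA_real_, length(culture$conc), n + 1L,
                  dimnames = list(names(culture$conc), NULL))

  # metabolite rules as plain vectors for the hot loop
  rMet <- rules$metabolite
  rLt <- rules$comparator == "lt"
  rThr <- rules$threshold
  rTgt <- match(rules$target, g)
  rMean <- rules$mean
  rSd <- rules$sd
  rLive <- !(rules$target %in% ko)

  doStep <- function(mu, v) {
    m2 <- drop(mats$W %*% mu) + mats$b
    if (sample) {
      m2 <- m2 + stats::rnorm(G, 0, mats$sigma)
      v2 <- rep(0, G)
    } else {
      v2 <- drop((mats$W^2) %*% v) + mats$sigma^2
    }
    if (length(koIdx)) {
      m2[koIdx] <- 0
      v2[koIdx] <- 0
    }
    list(m = m2, v = v2)
  }
  applyRules <- function(mu, v, conc) {
    applied <- integer(0)
    if (length(rMet)) {
      c0 <- conc[rMet]
      holds <- ifelse(rLt, c0 < rThr, c0 >= rThr) & rLive
      for (i in which(holds)) {   # later rules overwrite earlier (file order)
        j <- rTgt[i]
        mu[j] <- if (sample) stats::rnorm(1, rMean[i], rSd[i]) else rMean[i]
        v[j] <- if (sample) 0 else rSd[i]^2
        applied <- c(applied, j)
      }
    }
    list(m = mu, v = v, applied = applied)
  }

  run <- function() {
    mu <- dbn@initMean[g]
    v <- dbn@initSd[g]^2
    if (sample && any(v > 0)) {
      mu <- mu + stats::rnorm(G, 0, sqrt(v))
      v <- rep(0, G)
    }
    if (length(koIdx)) {
      mu[koIdx] <- 0
      v[koIdx] <- 0
    }
    ar <- applyRules(mu, v, culture$conc)
    mu <- ar$m; v <- ar$v
    RA[ar$applied, 1L] <<- TRUE
    M[, 1L] <<- mu
    Sd[, 1L] <<- sqrt(v)
    ctx <- metContext(met)
    X <- culture$biomass
    conc <- culture$conc
    Xv[1L] <<- X
    concM[, 1L] <<- conc
    for (t in seq_len(n)) {
      nxt <- doStep(mu, v)
      mu <- nxt$m; v <- nxt$v
      act <- setNames(mu, g)
      lb <- ctx$lb0
      ub <- ctx$ub0
      for (r in seq_along(ctx$rules)) {
        a <- evalGeneRule(ctx$rules[[r]], act, ko)
        j <- ctx$ruleIdx[r]
        lb[j] <- lb[j] * a
        ub[j] <- ub[j] * a
      }
      stp <- dfbaStepCtx(ctx, X, conc, lb, ub, dt, pfba = pfba)
      X <- stp$X
      conc <- stp$conc
      fluxes[, t] <<- stp$fluxes
      ar <- applyRules(mu, v, conc)
      mu <- ar$m; v <- ar$v
      RA[ar$applied, t + 1L] <<- TRUE
      M[, t + 1L] <<- mu
      Sd[, t + 1L] <<- sqrt(pmax(v, 0))
      Xv[t + 1L] <<- X
      concM[, t + 1L] <<- conc
    }
  }
  if (sample) withSeed(seed, run()) else run()
  cultDF <- data.frame(time_h = (0:n) * dt, biomass = Xv)
  for (m in rownames(concM)) cultDF[[m]] <- concM[m, ]

  traj <- new("GeneStateTrajectory", mean = M, sd = Sd, times = (0:n) * dt,
              direction = "forward")
  curve <- data.frame(time_h = cultDF$time_h, od560 = cultDF$biomass * odFactor)
  if ("glc_e" %in% names(cultDF)) curve$glucose_mM <- cultDF$glc_e
  # curves too short or too flat to phenotype get zero rates, flagged
  gp <- tryCatch(growthParameters(curve), error = function(e) {
    new("GrowthParameters", preRate = 0, postRate = 0, shiftTime = NA_real_,
        lag = max(curve$time_h), yieldOD = curve$od560[nrow(curve)],
        shiftDetected = FALSE)
  })
  new("SimulationResult", trajectory = traj, culture = cultDF, fluxes = fluxes,
      ruleApplied = RA, odFactor = odFactor, growth = gp)
}

#' Growth parameters of a simulated curve
#'
#' Applies the same estimator used on observed curves
#' ([growthParameters()]) to the simulated biomass curve -- a single code
#' path, so predicted and observed phenotypes are directly comparable.
#'
#' @param result a [SimulationResult-class].
#' @return a [GrowthParameters-class].
#' @export
predictedGrowthParams <- function(result) {
  result@growth
}

#' Export / import growth curves
#'
#' CSV dialect shared by predicted and observed curves: columns
#' \code{strain}, \code{replicate}, \code{time_h}, \code{od560},
#' \code{glucose_mM} (may be empty), UTF-8 with a mandatory header.
#'
#' @param curves data.frame in the dialect above (for a predicted curve from
#'   [simulateStrain()], see [cultureSeries()]).
#' @param path file path.
#' @export
writeGrowthCSV <- function(curves, path) {
  write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGrowthCSV
#' @export
readGrowthCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "replicate", "time_h", "od560")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("growth CSV lacks column(s): ", paste(missing, collapse = ", "))
  df
}
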