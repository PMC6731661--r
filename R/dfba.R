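#' @include fba.R
NULL

#' One dynamic-FBA step
#'
#' Static-optimisation DFBA: the medium first tightens each exchange's uptake
#' bound to \code{min(Vmax*c/(Km+c), c/(X*dt))} (Michaelis-Menten kinetics
#' capped by availability over the interval; buffered metabolites skip the
#' availability cap), the LP is solved maximising biomass (parsimonious
#' tie-break), biomass grows exponentially at the optimal rate,
#' \eqn{X' = X e^{\mu dt}}, and medium concentrations are updated with the
#' interval-average biomass \eqn{\bar X = (X' - X)/(\mu dt)}:
#' \eqn{c' = \max(0, c + v_{exch} \bar X dt)}. An infeasible LP falls back to
#' a zero-growth step and is flagged in the returned status.
#'
#' @param model a [MetabolicModel-class].
#' @param state culture state: list/one-row data.frame with \code{biomass}
#'   (gDW/L) and \code{conc}, a named vector of medium concentrations (mM).
#' @param bounds bounds data.frame (typically from [geneStatesToBounds()]).
#' @param dt step length in hours (> 0).
#' @param pfba parsimonious tie-break (default TRUE).
#' @return list with \code{state} (updated \code{biomass}, \code{conc}),
#'   \code{fluxes}, \code{mu}, \code{status}.
#' @export
dfbaStep <- function(model, state, bounds, dt, pfba = TRUE) {
  ctx <- metContext(model)
  lb <- bounds$lb[match(ctx$rid, bounds$id)]
  ub <- bounds$ub[match(ctx$rid, bounds$id)]
  out <- dfbaStepCtx(ctx, state$biomass, state$conc, lb, ub, dt, pfba)
  list(state = list(biomass = out$X, conc = out$conc),
       fluxes = setNames(out$fluxes, ctx$rid), mu = out$mu, status = out$status)
}

# hot-loop version on a precompiled context; conc is a named numeric vector
dfbaStepCtx <- function(ctx, X, conc, lb, ub, dt, pfba = TRUE) {
  stopifnot(dt > 0, X > 0)
  for (k in ctx$kin) {
    c0 <- conc[[k$metId]]
    cap <- k$vmax * c0 / (k$km + c0)
    if (!k$buffered) cap <- min(cap, c0 / (X * dt))
    j <- k$exIdx
    lb[j] <- max(lb[j], -cap)
    ub[j] <- max(ub[j], lb[j])
  }
  sol <- fbaCore(ctx, lb, ub, ctx$bioIdx)
  if (sol$status != "optimal") {
    return(list(X = X, conc = conc, fluxes = numeric(length(ctx$rid)),
                mu = 0, status = paste0("fallback:", sol$status)))
  }
  v <- sol$x
  mu <- max(v[ctx$bioIdx], 0)
  if (pfba) {
    if (mu <= 1e-12 && all(lb <= 1e-12) && all(ub >= -1e-12)) {
      v <- numeric(length(ctx$rid))   # v = 0 is feasible, hence parsimonious
    } else {
      vp <- pfbaCore(ctx, lb, ub, ctx$bioIdx, v[ctx$bioIdx])
      if (!is.null(vp)) v <- vp
    }
  }
  X1 <- X * exp(mu * dt)
  Xbar <- if (mu > 1e-12) (X1 - X) / (mu * dt) else X
  for (i in seq_along(ctx$tracked)) {
    j <- ctx$trackedEx[i]
    if (is.na(j)) next
    m <- ctx$tracked[i]
    conc[[m]] <- max(0, conc[[m]] + v[j] * Xbar * dt)
  }
  list(X = X1, conc = conc, fluxes = v, mu = mu, status = "optimal")
}

# exchange reaction id serving metabolite m (the exchange whose only
# stoichiometric entry is m), NA if none
exchangeFor <- function(model, m) {
  for (ex in model@exchangeIds) {
    st <- model@stoich[, ex]
    nz <- names(st)[st != 0]
    if (identical(nz, m)) return(ex)
  }
  NA_character_
}
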