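#' @include AllClasses.R
NULL

#' Preprocess replicate growth curves into one mean curve
#'
#' Per replicate: subtract the blank, clip at zero, median-smooth the OD with
#' a running window; then interpolate every replicate onto the common time
#' grid and average. Glucose columns are averaged the same way (without
#' blanking). Fewer than \code{minReps} replicates triggers a warning, not an
#' error. With \code{normalize = TRUE} the mean curve is divided by its
#' starting OD so strains can be paired on equal starting cultures.
#'
#' @param raw data.frame with columns \code{replicate}, \code{time_h},
#'   \code{od560} and optionally \code{glucose_mM}, for a single strain.
#' @param blank blank OD subtracted from every reading.
#' @param window median-filter window in samples (odd; default 5).
#' @param minReps replicate floor below which a warning is issued (default 8).
#' @param normalize divide by starting OD.
#' @return data.frame \code{time_h}, \code{od560} (and \code{glucose_mM}
#'   when present): the mean preprocessed curve.
#' @export
preprocessCurve <- function(raw, blank = 0, window = 5, minReps = 8,
                            normalize = FALSE) {
  if (!nrow(raw)) stop("no readings supplied")
  reps <- sort(unique(raw$replicate))
  if (length(reps) < minReps) {
    warning(sprintf("only %d replicate(s) (< %d); proceeding with what is available",
                    length(reps), minReps))
  }
  grid <- sort(unique(raw$time_h))
  hasGlc <- "glucose_mM" %in% names(raw) && any(!is.na(raw$glucose_mM))
  odM <- matrix(NA_real_, length(grid), length(reps))
  glM <- if (hasGlc) odM else NULL
  for (k in seq_along(reps)) {
    r <- raw[raw$replicate == reps[k], ]
    r <- r[order(r$time_h), ]
    od <- pmax(r$od560 - blank, 0)
    if (length(od) >= window) od <- stats::runmed(od, window)
    odM[, k] <- if (identical(r$time_h, grid)) od else {
      stats::approx(r$time_h, od, xout = grid)$y
    }
    if (hasGlc) {
      gl <- r$glucose_mM
      glM[, k] <- if (identical(r$time_h, grid)) gl else {
        stats::approx(r$time_h, gl, xout = grid)$y
      }
    }
  }
  out <- data.frame(time_h = grid, od560 = rowMeans(odM, na.rm = TRUE))
  if (hasGlc) out$glucose_mM <- rowMeans(glM, na.rm = TRUE)
  if (normalize && out$od560[1] > 0) out$od560 <- out$od560 / out$od560[1]
  out
}

#' Extract growth parameters from a growth curve
#'
#' Descriptive parameters of a (possibly biphasic) OD curve. The shift time
#' is the glucose-depletion time (first time glucose < \code{gMin}) when a
#' glucose series is present, otherwise the breakpoint of a two-segment
#' piecewise-linear fit to log OD chosen to minimise residual error. Pre- and
#' post-shift specific growth rates are the median pointwise slopes of log OD
#' inside each segment of the growth window (between lag and saturation,
#' trimmed one grid step around the shift), which is exact on clean
#' exponential phases and robust to the transition samples; rates are clipped
#' at 0. Lag is the time to exceed 1.05x the initial OD; yield is the final
#' OD. A shift is declared when the two-segment fit beats the single line in
#' an F-test at alpha = 0.05 and both segments carry at least 3 points.
#'
#' @param curve data.frame with \code{time_h}, \code{od560} and optionally
#'   \code{glucose_mM}; times strictly increasing, >= 6 points over > 2 h.
#' @param gMin glucose-depletion threshold in mM (default 0.1).
#' @param alpha F-test level for shift detection.
#' @return a [GrowthParameters-class].
#' @examples
#' t <- seq(0, 10, 0.5)
#' curve <- data.frame(time_h = t, od560 = 0.05 * exp(0.4 * t))
#' growthParameters(curve)  # pre-shift rate 0.4, no shift detected
#' @export
growthParameters <- function(curve, gMin = 0.1, alpha = 0.05) {
  t <- curve$time_h
  y <- curve$od560
  if (any(diff(t) <= 0)) stop("time points must be strictly increasing")
  if (length(t) < 6 || diff(range(t)) <= 2) {
    stop("need at least 6 time points spanning more than 2 h")
  }
  flat <- new("GrowthParameters", preRate = 0, postRate = 0,
              shiftTime = NA_real_, lag = t[length(t)],
              yieldOD = y[length(y)], shiftDetected = FALSE)
  if (max(y) <= 1.05 * max(y[1], 1e-12)) return(flat)

  eps <- max(y) * 1e-6
  ly <- log(pmax(y, eps))
  lag <- t[which(y > 1.05 * y[1])[1]]
  tSat <- t[which(y >= 0.99 * max(y))[1]]
  win <- which(t >= lag & t <= tSat)
  if (length(win) < 6) win <- which(t >= lag)
  if (length(win) < 6) win <- seq_along(t)

  glc <- if ("glucose_mM" %in% names(curve)) curve$glucose_mM else NULL
  shiftT <- NA_real_
  if (!is.null(glc) && any(glc < gMin, na.rm = TRUE)) {
    shiftT <- t[which(glc < gMin)[1]]
  } else {
    # two-segment piecewise-linear fit to log OD over the growth window
    best <- Inf
    for (k in win[3:(length(win) - 3)]) {
      i1 <- win[win <= k]
      i2 <- win[win > k]
      if (length(i1) < 3 || length(i2) < 3) next
      r1 <- stats::lm.fit(cbind(1, t[i1]), ly[i1])$residuals
      r2 <- stats::lm.fit(cbind(1, t[i2]), ly[i2])$residuals
      rss <- sum(r1^2) + sum(r2^2)
      if (rss < best - 1e-12) {
        best <- rss
        shiftT <- t[k]
      }
    }
  }

  medSlope <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- diff(ly[idx]) / diff(t[idx])
    max(0, stats::median(s))
  }
  dtGrid <- stats::median(diff(t))
  if (is.na(shiftT) || shiftT <= t[win[1]] || shiftT >= t[win[length(win)]]) {
    pre <- medSlope(win)
    return(new("GrowthParameters", preRate = pre, postRate = 0,
               shiftTime = NA_real_, lag = lag, yieldOD = y[length(y)],
               shiftDetected = FALSE))
  }
  i1 <- win[t[win] <= shiftT - dtGrid / 2]
  i2 <- win[t[win] >= shiftT + dtGrid]
  if (length(i1) < 3) i1 <- win[t[win] <= shiftT]
  if (length(i2) < 3) i2 <- win[t[win] > shiftT]
  preRate <- medSlope(i1)
  postRate <- medSlope(i2)

  detected <- FALSE
  j1 <- win[t[win] <= shiftT]
  j2 <- win[t[win] > shiftT]
  if (length(j1) >= 3 && length(j2) >= 3 && length(win) >= 7) {
    rssSingle <- sum(stats::lm.fit(cbind(1, t[win]), ly[win])$residuals^2)
    f1 <- stats::lm.fit(cbind(1, t[j1]), ly[j1])
    f2 <- stats::lm.fit(cbind(1, t[j2]), ly[j2])
    rssSplit <- sum(f1$residuals^2) + sum(f2$residuals^2)
    dfDen <- length(win) - 4
    Fstat <- ((rssSingle - rssSplit) / 2) / max(rssSplit / dfDen, 1e-300)
    # a detected shift needs both statistical support and a rate change
    # beyond instrument resolution (0.01/h), so an exactly exponential curve
    # is never declared biphasic on numerical noise
    detected <- stats::pf(Fstat, 2, dfDen, lower.tail = FALSE) < alpha &&
      abs(f1$coefficients[2] - f2$coefficients[2]) > 0.01
  }
  new("GrowthParameters", preRate = preRate, postRate = postRate,
      shiftTime = shiftT, lag = lag, yieldOD = y[length(y)],
      shiftDetected = detected)
}

#' Compare two models' per-strain prediction errors
#'
#' The evaluation arithmetic for model comparison: given paired per-strain
#' error vectors for model A (reference) and model B (challenger), the ratio
#' is the relative reduction of error achieved by B,
#' \eqn{(\bar e_A - \bar e_B) / \bar e_A}, and the p-value is a two-sided
#' Wilcoxon signed-rank test on the paired errors (exact for n <= 25 without
#' ties, normal approximation with continuity correction otherwise;
#' zero differences dropped).
#'
#' @param errorsA,errorsB paired non-negative error vectors over the same
#'   strains (same length, >= 5).
#' @return list with \code{ratio}, \code{p}, \code{n} (pairs used).
#' @export
compareModels <- function(errorsA, errorsB) {
  if (length(errorsA) != length(errorsB)) stop("error vectors must be paired (equal length)")
  if (length(errorsA) < 5) stop("need at least 5 paired strains")
  ratio <- if (mean(errorsA) > 0) (mean(errorsA) - mean(errorsB)) / mean(errorsA) else 0
  d <- errorsA - errorsB
  d <- d[d != 0]
  if (!length(d)) return(list(ratio = ratio, p = 1, n = 0L))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(errorsA, errorsB, paired = TRUE, exact = exact,
                       correct = TRUE)$p.value)
  list(ratio = ratio, p = p, n = length(d))
}
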