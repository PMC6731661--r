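#' @include adarev.R design.R elsa.R virtual-lab.R
NULL

#' Run one closed-loop model-improvement cycle
#'
#' Orchestrates design -> (virtual) execution -> refinement -> evaluation:
#' \enumerate{
#'   \item a held-out evaluation strain set is drawn first (seeded), and the
#'     design may only select from the remaining pool, so evaluation strains
#'     are always disjoint from refinement strains (audited in the report);
#'   \item the design method picks \code{k} deletant strains:
#'     \code{"adactive"} (forward/backward divergence against the observed
#'     wild-type curve), \code{"coregmine"} (border regulators of
#'     antagonistic coregulation subgraphs, padded with top divergence if
#'     short), \code{"adana"} (largest post-shift disagreement with
#'     \code{config$modelB}), or \code{"random"};
#'   \item the virtual lab executes the experiments (replicate noisy curves,
#'     phenotyped by the same estimator as predictions);
#'   \item [refineModel()] revises the working model against the
#'     observations;
#'   \item before/after models are compared on the held-out strains
#'     ([postshiftError()] + [compareModels()]).
#' }
#' Every stochastic stage derives its seed from \code{config$seed}; a failed
#' stage is recorded in the report and later stages are skipped.
#'
#' @param config a list (or path to a YAML file with the same fields):
#'   \describe{
#'     \item{truth}{ground-truth [HybridModel-class], or a path to one, or
#'       NULL to generate from \code{lab}.}
#'     \item{working}{the model to improve (object or path); defaults to
#'       \code{truth}.}
#'     \item{method}{\code{"adactive"}, \code{"coregmine"}, \code{"adana"},
#'       \code{"random"}.}
#'     \item{k}{number of designed experiments.}
#'     \item{heldoutK}{number of held-out evaluation strains (default 10).}
#'     \item{evalPool}{pool the held-out strains are drawn from (default:
#'       all genes of the working model).}
#'     \item{maxEvals}{refinement budget (default 8).}
#'     \item{seed}{integer master seed.}
#'     \item{lab}{list of [labConfig()] overrides.}
#'     \item{candidates}{knockable pool (default: all regulators).}
#'     \item{modelB}{rival model for \code{method = "adana"}.}
#'   }
#' @return a \code{cycleReport} list: design, strains, held-out strains,
#'   error before/after, \code{ratio}, \code{p}, the revision trace, the
#'   refined model, and an audit flag.
#' @export
runCycle <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  lab <- do.call(labConfig, c(config$lab %||% list(),
                              if (is.null(config$lab$seed)) list(seed = config$seed %||% 1)))
  seed <- config$seed %||% 1
  method <- match.arg(config$method %||% "adactive",
                      c("adactive", "coregmine", "adana", "random"))
  k <- config$k %||% 20
  heldoutK <- config$heldoutK %||% 10
  report <- list(method = method, k = k, seed = seed, stages = character(0))
  fail <- function(stage, e) {
    report$stages[stage] <<- paste("failed:", conditionMessage(e))
    report
  }
  asModel <- function(x) if (is.character(x)) loadHybridModel(x) else x

  truth <- tryCatch({
    m <- asModel(config$truth)
    if (is.null(m)) m <- generateGroundTruth(lab)
    m
  }, error = function(e) NULL)
  if (is.null(truth)) return(fail("truth", simpleError("cannot obtain ground truth")))
  working <- asModel(config$working) %||% truth

  pool <- config$candidates %||% regulators(working)
  # evaluation strains come from the whole knockable gene set, so holding
  # them out bites as little as possible into the (regulator) design pool
  evalPool <- config$evalPool %||% genes(working)
  heldout <- randomDesign(evalPool, min(heldoutK, length(evalPool)),
                          seed = subSeed(seed, 7L))
  designPool <- setdiff(pool, heldout)
  report$heldout <- heldout

  strains <- tryCatch(switch(
    method,
    random = randomDesign(designPool, min(k, length(designPool)),
                          seed = subSeed(seed, 11L)),
    adactive = {
      wtObs <- observeStrains(truth, "WT", lab)
      wtGp <- new("GrowthParameters", preRate = wtObs$preRate, postRate = wtObs$postRate,
                  shiftTime = wtObs$shiftTime, lag = 0, yieldOD = 0,
                  shiftDetected = wtObs$shiftDetected)
      rk <- adactiveRank(working, wtGp, horizon = lab$horizon, dt = lab$dt)
      head(rk$gene[rk$gene %in% designPool], k)
    },
    coregmine = {
      expr <- generateExpressionDataset(truth, lab)
      tg <- modelTargets(working)
      sel <- if (length(tg) >= 2) {
        prof <- influenceProfiles(expr, tg)
        coregmineSelect(prof, tg)
      } else character(0)
      sel <- intersect(sel, designPool)
      if (length(sel) < k) {
        wtObs <- observeStrains(truth, "WT", lab)
        wtGp <- new("GrowthParameters", preRate = wtObs$preRate,
                    postRate = wtObs$postRate, shiftTime = wtObs$shiftTime,
                    lag = 0, yieldOD = 0, shiftDetected = wtObs$shiftDetected)
        rk <- adactiveRank(working, wtGp, horizon = lab$horizon, dt = lab$dt)
        sel <- unique(c(sel, rk$gene[rk$gene %in% designPool]))
      }
      head(sel, k)
    },
    adana = {
      modelB <- asModel(config$modelB)
      if (is.null(modelB)) stop("method 'adana' needs config$modelB")
      adanaDisagreement(working, modelB, designPool, k,
                        horizon = lab$horizon, dt = lab$dt)$gene
    }), error = function(e) NULL)
  if (is.null(strains)) return(fail("design", simpleError("design stage failed")))
  report$strains <- strains
  report$stages["design"] <- "ok"

  obs <- tryCatch(observeStrains(truth, strains, lab), error = function(e) NULL)
  if (is.null(obs)) return(fail("execute", simpleError("virtual experiments failed")))
  report$stages["execute"] <- "ok"

  ref <- tryCatch(refineModel(working, obs, maxEvals = config$maxEvals %||% 8,
                              horizon = lab$horizon, dt = lab$dt),
                  error = function(e) NULL)
  if (is.null(ref)) return(fail("refine", simpleError("refinement failed")))
  report$trace <- ref$trace
  report$stages["refine"] <- "ok"

  hoObs <- tryCatch(observeStrains(truth, heldout, lab), error = function(e) NULL)
  if (is.null(hoObs)) return(fail("evaluate", simpleError("held-out observation failed")))
  errB <- postshiftError(working, hoObs, horizon = lab$horizon, dt = lab$dt)
  errA <- postshiftError(ref$model, hoObs, horizon = lab$horizon, dt = lab$dt)
  common <- intersect(names(errB$errors), names(errA$errors))
  cmp <- if (length(common) >= 5) compareModels(errB$errors[common], errA$errors[common])
         else list(ratio = NA_real_, p = NA_real_, n = length(common))
  report$stages["evaluate"] <- "ok"
  report$errorBefore <- errB$mae
  report$errorAfter <- errA$mae
  report$heldoutErrorsBefore <- errB$errors
  report$heldoutErrorsAfter <- errA$errors
  report$ratio <- cmp$ratio
  report$p <- cmp$p
  report$refined <- ref$model
  report$audit <- list(disjoint = !any(strains %in% heldout))
  class(report) <- "cycleReport"
  report
}

# activated / repressed target sets implied by a model's signed edges
modelTargets <- function(model) {
  e <- dbnEdges(model)
  out <- list()
  for (r in unique(e$parent)) {
    out[[r]] <- list(activated = e$child[e$parent == r & e$weight > 0],
                     repressed = e$child[e$parent == r & e$weight < 0])
  }
  out
}

#' @export
print.cycleReport <- function(x, ...) {
  cat("Closed-loop cycle report\n")
  cat("  method:", x$method, " k:", x$k, " seed:", x$seed, "\n")
  cat("  stages:", paste(names(x$stages), x$stages, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$errorBefore)) {
    cat(sprintf("  held-out post-shift MAE: %.4f -> %.4f (ratio %.3f, Wilcoxon p %.3g)\n",
                x$errorBefore, x$errorAfter, x$ratio, x$p))
    cat(sprintf("  revisions accepted: %d\n", sum(x$trace$action == "accepted")))
  }
  invisible(x)
}

#' Persist a cycle report
#'
#' Writes the refined model (JSON), the revision trace (TSV), the experiment
#' requests (CSV) and a YAML summary into a directory.
#'
#' @param report a \code{cycleReport} from [runCycle()].
#' @param dir output directory (created if needed).
#' @export
writeCycleReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$refined)) {
    saveHybridModel(report$refined, file.path(dir, "refined_model.json"))
  }
  if (!is.null(report$trace)) writeRevisionTrace(report$trace, file.path(dir, "trace.tsv"))
  if (!is.null(report$strains)) {
    writeExperimentRequests(report$strains, report$method,
                            path = file.path(dir, "requests.csv"))
  }
  summ <- report[c("method", "k", "seed", "strains", "heldout", "errorBefore",
                   "errorAfter", "ratio", "p")]
  summ$stages <- as.list(report$stages)
  yaml::write_yaml(summ, file.path(dir, "report.yaml"))
  invisible(dir)
}
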