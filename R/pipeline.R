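# Orchestration: sample -> screen -> simulate -> perturb -> summarise.

#' Run a full robustness experiment
#'
#' Samples steady-state parameter sets bottom-up, screens them for an
#' unstable steady state, integrates the unstable ones, detects and confirms
#' regular oscillations, perturbs every perturbable parameter by `delta`,
#' and keeps accumulating until `targetAccepted` parameter sets have yielded
#' confirmed sustained oscillations for the unperturbed system and every
#' perturbation. All randomness flows from `seed`; two runs with the same
#' configuration and seed produce identical records.
#'
#' @param model a [ModelSpec-class].
#' @param targetAccepted number of fully accepted parameter sets (2,500 in
#'   the full design; `quick = TRUE` switches to 500 for desk-scale runs).
#' @param config a [SampleConfig-class].
#' @param policy an [IntegrationPolicy-class].
#' @param delta relative parameter perturbation (default +2\%).
#' @param seed RNG seed for the experiment.
#' @param maxSampled abort threshold: if this many draws are consumed before
#'   the target is reached, the run stops with an error carrying the
#'   accounting so far.
#' @param quick use the desk-scale target of 500 accepted sets.
#' @param batchSize draws per sampling batch (fixed so runs are
#'   deterministic).
#' @param verbose print progress.
#' @return a [RobustnessExperiment-class].
#' @examples
#' \donttest{
#' ex <- runExperiment(chainModel("positive"), targetAccepted = 5, seed = 1)
#' sensitivityRecords(ex)
#' }
#' @export
runExperiment <- function(model, targetAccepted = 2500,
                          config = sampleConfig(),
                          policy = integrationPolicy(),
                          delta = 0.02, seed = NULL,
                          maxSampled = 2e7, quick = FALSE,
                          batchSize = 5000, verbose = FALSE) {
  if (quick) targetAccepted <- 500
  if (targetAccepted < 1) stop("targetAccepted must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pack <- .packModel(model)
  nEx <- length(model@moieties)
  b <- .speciesLogBounds(model, config)
  iv <- log10(config@interval)

  acc <- list(nSampled = 0, nSamplingFailures = 0, nUnstable = 0,
              nOscillating = 0, nAccepted = 0,
              discards = c(stable = 0, `not-regular` = 0,
                           `confirm-mismatch` = 0, `solver-failure` = 0,
                           `perturbed-not-regular` = 0,
                           `perturbed-confirm-mismatch` = 0,
                           `perturbed-solver-failure` = 0))
  records <- list()
  coefs <- list()
  drawBase <- 0

  while (acc$nAccepted < targetAccepted) {
    if (acc$nSampled >= maxSampled) {
      cond <- structure(class = c("oscrobustStarvation", "error",
                                  "condition"),
                        list(message = sprintf(
                          "sampler starvation: %d accepted of %d after %g draws",
                          acc$nAccepted, targetAccepted, acc$nSampled),
                          call = sys.call(), accounting = acc))
      stop(cond)
    }
    st <- cppSampleStates(pack, as.integer(batchSize), b$lo, b$hi,
                          iv[1], iv[2], iv[1], iv[2],
                          as.integer(config@maxFlowResampleAttempts),
                          matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0))
    mr <- rep(NA_real_, batchSize)
    ok <- st$ok
    if (any(ok))
      mr[ok] <- .maxRePartBatch(pack, st$S0[, ok, drop = FALSE],
                                st$k[, ok, drop = FALSE],
                                st$theta[, ok, drop = FALSE], nEx)
    for (i in seq_len(batchSize)) {
      acc$nSampled <- acc$nSampled + 1
      if (!ok[i]) {
        acc$nSamplingFailures <- acc$nSamplingFailures + 1
        next
      }
      if (is.na(mr[i]) || mr[i] <= .MARGINAL_TOL) {
        acc$discards[["stable"]] <- acc$discards[["stable"]] + 1
        next
      }
      acc$nUnstable <- acc$nUnstable + 1
      set <- .setFromBatch(model, st, i, drawIndex = drawBase + i)
      res <- analyzeSet(model, set, delta, policy)
      if (res$status %in% c("not-regular", "confirm-mismatch",
                            "solver-failure")) {
        acc$discards[[res$status]] <- acc$discards[[res$status]] + 1
        next
      }
      if (res$status != "accepted") {   # perturbed-* discards
        acc$nOscillating <- acc$nOscillating + 1
        if (res$status %in% names(acc$discards))
          acc$discards[[res$status]] <- acc$discards[[res$status]] + 1
        next
      }
      acc$nOscillating <- acc$nOscillating + 1
      acc$nAccepted <- acc$nAccepted + 1
      res$record$setId <- acc$nAccepted
      res$coefficients$setId <- acc$nAccepted
      records[[acc$nAccepted]] <- res$record
      coefs[[acc$nAccepted]] <- res$coefficients
      if (verbose && acc$nAccepted %% 50 == 0)
        message(sprintf("accepted %d / %d (sampled %g)", acc$nAccepted,
                        targetAccepted, acc$nSampled))
      if (acc$nAccepted >= targetAccepted) break
    }
    drawBase <- drawBase + batchSize
  }

  new("RobustnessExperiment",
      model = model@name,
      records = do.call(rbind, records),
      coefficients = do.call(rbind, coefs),
      accounting = acc,
      config = list(interval = config@interval,
                    probabilityInterval = config@probabilityInterval,
                    maxFlowResampleAttempts = config@maxFlowResampleAttempts,
                    rtol = policy@rtol, atol = policy@atol,
                    maxTime = policy@maxTime, delta = delta,
                    seed = if (is.null(seed)) NA_real_ else seed,
                    targetAccepted = targetAccepted,
                    batchSize = batchSize))
}

setMethod("sensitivityRecords", "RobustnessExperiment",
          function(object) object@records)

setMethod("sensitivityCoefficientTable", "RobustnessExperiment",
          function(object) object@coefficients)

setMethod("runAccounting", "RobustnessExperiment",
          function(object) object@accounting)

setMethod("show", "RobustnessExperiment", function(object) {
  cat("RobustnessExperiment:", object@model, "\n")
  a <- object@accounting
  cat(sprintf("  accepted %d sets (sampled %g, unstable %d, oscillating %d)\n",
              a$nAccepted, a$nSampled, a$nUnstable, a$nOscillating))
  if (nrow(object@records)) {
    cat(sprintf("  sigma_T: median %.3g (90%% range %.3g)\n",
                median(object@records$sigmaT),
                diff(unname(quantile(object@records$sigmaT, c(0.05, 0.95))))))
    cat(sprintf("  sigma_A: median %.3g (90%% range %.3g)\n",
                median(object@records$sigmaA),
                diff(unname(quantile(object@records$sigmaA, c(0.05, 0.95))))))
  }
  invisible(NULL)
})

#' Compare sensitivity distributions across model variants
#'
#' Pairwise fold changes of medians and 90\% data ranges plus rank-sum
#' p-values, for both the period and the amplitude sensitivity.
#'
#' @param experiments named list of [RobustnessExperiment-class] objects
#'   (>= 2).
#' @return data.frame with one row per ordered pair and metric.
#' @export
compareVariants <- function(experiments) {
  if (length(experiments) < 2)
    stop("at least two completed runs are required")
  nm <- names(experiments)
  if (is.null(nm))
    nm <- vapply(experiments, function(e) e@model, character(1))
  rows <- list()
  for (i in seq_along(experiments)) for (j in seq_along(experiments)) {
    if (i == j) next
    for (metric in c("sigmaT", "sigmaA")) {
      a <- experiments[[i]]@records[[metric]]
      b <- experiments[[j]]@records[[metric]]
      sa <- summarizeDistribution(a)
      sb <- summarizeDistribution(b)
      rows[[length(rows) + 1]] <- data.frame(
        model_a = nm[i], model_b = nm[j], metric = metric,
        fold_median = foldChange(sa, sb, "median"),
        fold_range90 = if (sb@range90 > 0)
          foldChange(sa, sb, "range90") else NA_real_,
        p_value = compareDistributions(a, b))
    }
  }
  do.call(rbind, rows)
}
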