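# Bottom-up Monte-Carlo sampling of steady states.

#' Sampling configuration
#'
#' @param interval concentration/flow/nl-parameter sampling interval for
#'   log10-uniform draws; default `(1e-3, 1e3)` (seven orders of magnitude).
#' @param probabilityInterval interval used instead for species tagged as
#'   probabilities; default `(1e-3, 1)`.
#' @param seed optional RNG seed applied by [sampleStates()] before drawing;
#'   `NA` leaves the RNG state untouched.
#' @param maxFlowResampleAttempts cap on flow re-draws per state; a state
#'   whose computed flows never land inside the interval within this many
#'   attempts counts as a sampling failure.
#' @return a [SampleConfig-class].
#' @export
sampleConfig <- function(interval = c(1e-3, 1e3),
                         probabilityInterval = c(1e-3, 1),
                         seed = NA_real_,
                         maxFlowResampleAttempts = 1000) {
  obj <- new("SampleConfig", interval = as.numeric(interval),
             probabilityInterval = as.numeric(probabilityInterval),
             seed = as.numeric(seed),
             maxFlowResampleAttempts = as.numeric(maxFlowResampleAttempts))
  validObject(obj)
  obj
}

.speciesLogBounds <- function(model, config) {
  lo <- ifelse(model@species$domain == "probability",
               log10(config@probabilityInterval[1]),
               log10(config@interval[1]))
  hi <- ifelse(model@species$domain == "probability",
               log10(config@probabilityInterval[2]),
               log10(config@interval[2]))
  list(lo = lo, hi = hi)
}

#' Draw steady-state concentrations
#'
#' Concentrations are drawn log10-uniformly on the configured interval;
#' probability-domain species are drawn on the probability interval.
#'
#' @param model a [ModelSpec-class].
#' @param n number of draws.
#' @param config a [SampleConfig-class].
#' @return an `nSpecies x n` matrix.
#' @export
sampleConcentrations <- function(model, n = 1, config = sampleConfig()) {
  b <- .speciesLogBounds(model, config)
  m <- nSpecies(model)
  out <- matrix(10^(b$lo + runif(m * n) * (b$hi - b$lo)), m, n)
  rownames(out) <- speciesNames(model)
  out
}

#' Draw a balanced steady-state flow vector
#'
#' Selects `M - rank(eta)` independent flows in random order (flows are kept
#' as free draws only while the remaining columns of the stoichiometric
#' matrix still determine the dependent flows uniquely), draws them
#' log10-uniformly, and solves the steady-state condition
#' \eqn{\eta \nu^0 = 0} for the rest. The whole draw is repeated until every
#' computed flow also lies inside the interval.
#'
#' @inheritParams sampleConcentrations
#' @return named flow vector of length `nFlows(model)`.
#' @export
sampleFlows <- function(model, config = sampleConfig()) {
  st <- sampleStates(model, 1, config, setSeed = FALSE)
  if (!st$ok[1])
    stop("flow sampling failed after ", config@maxFlowResampleAttempts,
         " attempts")
  out <- st$nu0[, 1]
  names(out) <- rateCoefficientNames(model)
  out
}

#' Back-solve rate coefficients from a sampled state
#'
#' Every flow is linear in its rate coefficient,
#' \eqn{\nu_j = k_j g_j(S,\theta)}, so for a sampled steady state the rate
#' coefficients are the unique solution \eqn{k_j = \nu^0_j / g_j(S^0,\theta)}.
#'
#' @param model a [ModelSpec-class].
#' @param S0 steady-state concentrations.
#' @param nu0 balanced steady-state flows.
#' @param theta nl-parameter values (named or in model order).
#' @return named rate-coefficient vector.
#' @export
solveRateCoefficients <- function(model, S0, nu0, theta = numeric(0)) {
  .checkState(model, S0)
  nl <- model@nlParameters$name
  th <- if (length(nl)) {
    if (!is.null(names(theta))) unname(theta[nl]) else as.numeric(theta)
  } else numeric(0)
  g <- cppGFactors(.packModel(model), as.numeric(S0), th)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("kinetic factor g_j is not strictly positive at this state")
  k <- as.numeric(nu0) / g
  names(k) <- rateCoefficientNames(model)
  k
}

#' Sample steady-state parameter sets bottom-up
#'
#' Composes the three draws (concentrations, balanced flows, nl-parameters)
#' and the deterministic back-solve of the rate coefficients. `sampleStates()`
#' returns a columnar batch; `sampleState()` returns a single
#' [SampledParameterSet-class].
#'
#' @param model a [ModelSpec-class].
#' @param n number of states to draw.
#' @param config a [SampleConfig-class].
#' @param setSeed apply `config@seed` (when not `NA`) before drawing.
#' @return `sampleStates()`: list with matrices `S0` (species x n), `nu0`
#'   (flows x n), `theta`, `k`, integer vector `attempts`, logical `ok`
#'   (`FALSE` marks sampling failures, counted but not fatal), and the
#'   stoichiometric `rank` used. `sampleState()`: a
#'   [SampledParameterSet-class].
#' @examples
#' mod <- chainModel("negative")
#' st <- sampleStates(mod, 10, sampleConfig(seed = 1))
#' max(abs(stoichiometry(mod) %*% st$nu0))  # flow balance
#' @export
sampleStates <- function(model, n, config = sampleConfig(), setSeed = TRUE) {
  if (setSeed && !is.na(config@seed)) set.seed(config@seed)
  b <- .speciesLogBounds(model, config)
  iv <- log10(config@interval)
  out <- cppSampleStates(.packModel(model), as.integer(n), b$lo, b$hi,
                         iv[1], iv[2], iv[1], iv[2],
                         as.integer(config@maxFlowResampleAttempts),
                         matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0))
  rownames(out$S0) <- speciesNames(model)
  rownames(out$nu0) <- rateCoefficientNames(model)
  rownames(out$k) <- rateCoefficientNames(model)
  if (nrow(model@nlParameters))
    rownames(out$theta) <- model@nlParameters$name
  out$model <- model@name
  out
}

#' @rdname sampleStates
#' @export
sampleState <- function(model, config = sampleConfig()) {
  st <- sampleStates(model, 1, config)
  if (!st$ok[1])
    stop("sampling failed after ", config@maxFlowResampleAttempts,
         " flow attempts")
  .setFromBatch(model, st, 1)
}

.setFromBatch <- function(model, batch, i, drawIndex = i) {
  theta <- if (nrow(model@nlParameters)) batch$theta[, i] else numeric(0)
  if (length(theta)) names(theta) <- model@nlParameters$name
  new("SampledParameterSet",
      S0 = stats::setNames(batch$S0[, i], speciesNames(model)),
      nu0 = stats::setNames(batch$nu0[, i], rateCoefficientNames(model)),
      theta = theta,
      k = stats::setNames(batch$k[, i], rateCoefficientNames(model)),
      model = model@name, drawIndex = as.numeric(drawIndex))
}

setMethod("parameterVector", "SampledParameterSet", function(object)
  c(object@k, object@theta))

setMethod("steadyState", "SampledParameterSet", function(object) object@S0)

setMethod("steadyStateFlows", "SampledParameterSet",
          function(object) object@nu0)

setMethod("show", "SampledParameterSet", function(object) {
  cat("SampledParameterSet for model", object@model,
      sprintf("(draw %d)\n", as.integer(object@drawIndex)))
  cat("  S0:   ", paste(signif(object@S0, 4), collapse = " "), "\n")
  cat("  nu0:  ", paste(signif(object@nu0, 4), collapse = " "), "\n")
  if (length(object@theta))
    cat("  theta:", paste(signif(object@theta, 4), collapse = " "), "\n")
  cat("  k:    ", paste(signif(object@k, 4), collapse = " "), "\n")
  invisible(NULL)
})
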