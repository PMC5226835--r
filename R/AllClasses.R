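# S4 classes for the oscillator-robustness workflow.

#' Flow law of a single reaction
#'
#' A flow \eqn{\nu_j = k_j \, g_j(S, \theta)} is linear in its rate
#' coefficient \eqn{k_j} (a rate constant or maximal velocity). The kinetic
#' factor \eqn{g_j} is a product of elementary factors, each a list with a
#' `type` field:
#' \describe{
#'   \item{`power`}{`S^e`, mass action; fields `species`, `exponent`
#'     (a number, or the name of a cooperativity parameter).}
#'   \item{`michaelis_menten`}{`S/(S + K)`; fields `species`, `km`
#'     (nl-parameter name).}
#'   \item{`hill_activation`}{`x^n/(1 + x^n)` with `x = S/K`; fields
#'     `species`, `constant`, `exponent`.}
#'   \item{`hill_inhibition`}{`1/(1 + x^n)`; fields as above.}
#'   \item{`transcription_switch`}{`(Sa + c)/(K (1 + (Si/Ki)^p) + Sa + c)`,
#'     an activator/inhibitor transcription term; fields `activator`,
#'     `inhibitor`, `constant`, `inhibitionConstant`, `basal`, `exponent`.}
#' }
#' All factors are strictly positive for positive concentrations and
#' parameters, so every flow is positive.
#'
#' @slot rateCoefficient name of the parameter entering the flow linearly.
#' @slot factors list of factor descriptors (see Details).
#' @slot regulators names of species entering \eqn{g_j} without being
#'   consumed by the flow.
#' @exportClass FlowLaw
setClass("FlowLaw", representation(
  rateCoefficient = "character",
  factors = "list",
  regulators = "character"
))

#' Declarative ODE oscillator model
#'
#' A complete oscillator definition \eqn{dS_i/dt = \sum_j \eta_{ij} \nu_j}:
#' species, an \eqn{m \times M} stoichiometric matrix (more flows than
#' species), one [FlowLaw] per flow, the nl-parameters (Michaelis constants,
#' inhibition/activation constants; sampled and perturbed), and the fixed
#' cooperativity parameters (Hill coefficients; neither sampled nor
#' perturbed).
#'
#' @slot name model identifier.
#' @slot species data.frame with columns `name` and `domain`
#'   (`"concentration"` or `"probability"`).
#' @slot stoichiometry integer matrix \eqn{\eta}, species by flows.
#' @slot flows list of [FlowLaw] objects, one per column of `stoichiometry`.
#' @slot nlParameters data.frame with columns `name` and `role`
#'   (`"michaelis"` or `"regulation"`).
#' @slot cooperativity named numeric vector of fixed parameters.
#' @slot moieties list of conservation relations, each
#'   `list(species = <character>, total = <numeric>)`.
#' @slot referenceParameters named numeric vector (rate coefficients and
#'   nl-parameters) published with the model, or empty.
#' @slot referenceState named numeric starting state for the reference
#'   parameter set, or empty.
#' @exportClass ModelSpec
setClass("ModelSpec", representation(
  name = "character",
  species = "data.frame",
  stoichiometry = "matrix",
  flows = "list",
  nlParameters = "data.frame",
  cooperativity = "numeric",
  moieties = "list",
  referenceParameters = "numeric",
  referenceState = "numeric"
))

setValidity("ModelSpec", function(object) {
  msgs <- character(0)
  m <- nrow(object@stoichiometry)
  M <- ncol(object@stoichiometry)
  if (nrow(object@species) != m)
    msgs <- c(msgs, "species table and stoichiometry rows disagree")
  if (length(object@flows) != M)
    msgs <- c(msgs, "one FlowLaw per stoichiometry column is required")
  if (M <= m)
    msgs <- c(msgs, "the number of flows must exceed the number of species")
  if (!all(vapply(object@flows, is, logical(1), "FlowLaw")))
    msgs <- c(msgs, "flows must be FlowLaw objects")
  r <- qr(object@stoichiometry)$rank
  expected <- m - length(object@moieties)
  if (r != expected)
    msgs <- c(msgs, sprintf(
      "stoichiometry rank is %d but %d expected (%d species, %d conserved moieties)",
      r, expected, m, length(object@moieties)))
  if (!all(object@species$domain %in% c("concentration", "probability")))
    msgs <- c(msgs, "species domain must be 'concentration' or 'probability'")
  kn <- vapply(object@flows, function(f) f@rateCoefficient, character(1))
  if (anyDuplicated(c(kn, object@nlParameters$name)))
    msgs <- c(msgs, "parameter names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Sampling configuration
#'
#' Intervals for log10-uniform bottom-up sampling of steady-state
#' concentrations, flows and nl-parameters. Species tagged as probabilities
#' are drawn on `probabilityInterval` instead.
#'
#' @slot interval numeric length 2, default `(1e-3, 1e3)`.
#' @slot probabilityInterval numeric length 2, default `(1e-3, 1)`.
#' @slot seed optional RNG seed (`NA` to leave the RNG state alone).
#' @slot maxFlowResampleAttempts cap on flow re-draws per state before the
#'   draw is counted as a sampling failure.
#' @exportClass SampleConfig
setClass("SampleConfig", representation(
  interval = "numeric",
  probabilityInterval = "numeric",
  seed = "numeric",
  maxFlowResampleAttempts = "numeric"
))

setValidity("SampleConfig", function(object) {
  msgs <- character(0)
  iv <- object@interval
  pv <- object@probabilityInterval
  if (length(iv) != 2 || !(iv[1] > 0 && iv[1] < iv[2]))
    msgs <- c(msgs, "interval must satisfy 0 < low < high")
  if (length(pv) != 2 || !(pv[1] > 0 && pv[1] < pv[2] && pv[2] <= 1))
    msgs <- c(msgs, "probabilityInterval must lie in (0, 1]")
  if (object@maxFlowResampleAttempts < 1)
    msgs <- c(msgs, "maxFlowResampleAttempts must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' One sampled steady-state parameter set
#'
#' Holds the sampled steady-state concentrations `S0`, the balanced flow
#' vector `nu0` (satisfying \eqn{\eta \nu^0 = 0}), the sampled nl-parameters
#' `theta`, and the back-solved rate coefficients
#' \eqn{k_j = \nu^0_j / g_j(S^0, \theta)}.
#'
#' @slot S0 named steady-state concentration vector.
#' @slot nu0 named steady-state flow vector.
#' @slot theta named nl-parameter vector (may be empty).
#' @slot k named rate-coefficient vector.
#' @slot model name of the generating [ModelSpec].
#' @slot drawIndex 1-based index of the draw within its sampling stream.
#' @exportClass SampledParameterSet
setClass("SampledParameterSet", representation(
  S0 = "numeric",
  nu0 = "numeric",
  theta = "numeric",
  k = "numeric",
  model = "character",
  drawIndex = "numeric"
))

#' Linear stability classification of a sampled steady state
#'
#' @slot eigenvalues complex Jacobian spectrum (conservation-induced zero
#'   modes excluded for models with conserved moieties).
#' @slot classification `"stable"` or `"unstable"`.
#' @slot maxRealPart largest real part among the classified eigenvalues.
#' @slot marginal TRUE when `|maxRealPart|` is below the marginal tolerance;
#'   such borderline states are conservatively classified stable.
#' @exportClass StabilityResult
setClass("StabilityResult", representation(
  eigenvalues = "complex",
  classification = "character",
  maxRealPart = "numeric",
  marginal = "logical"
))

#' Integration and detection policy
#'
#' @slot rtol relative integration tolerance (detection pass).
#' @slot atol absolute integration tolerance (detection pass).
#' @slot probeSteps computation budget (accepted steps) given to each solver
#'   during the dual-solver probe; the solver that advances further in model
#'   time for this fixed work continues.
#' @slot maxTime integration is abandoned beyond this time horizon.
#' @slot maxSteps deterministic computation budget (accepted solver steps per
#'   run); replaces a wall-clock cap so results are machine-independent.
#' @slot relMaxPrecision relative precision within which five consecutive
#'   maxima must agree.
#' @slot relIntervalPrecision relative precision within which the four
#'   inter-maximum intervals must agree.
#' @slot confirmAgreement relative agreement required between the detection
#'   pass and the tightened confirmation pass for period and amplitude.
#' @slot confirmHorizon length of the tightened confirmation integration of
#'   the unperturbed system, in multiples of the detected period.
#' @slot perturbedConfirmHorizon confirmation length for perturbed systems;
#'   shorter by default because the unperturbed pass has already established
#'   the limit cycle and a 2\% parameter change deforms it only slightly.
#' @exportClass IntegrationPolicy
setClass("IntegrationPolicy", representation(
  rtol = "numeric",
  atol = "numeric",
  probeSteps = "numeric",
  maxTime = "numeric",
  maxSteps = "numeric",
  relMaxPrecision = "numeric",
  relIntervalPrecision = "numeric",
  confirmAgreement = "numeric",
  confirmHorizon = "numeric",
  perturbedConfirmHorizon = "numeric"
))

#' Detected oscillation with period and amplitudes
#'
#' @slot period oscillation period `T` (time between two equal maxima of the
#'   reference species).
#' @slot amplitudes per-species amplitudes `A_i` (max minus min over one
#'   period).
#' @slot meanAmplitude arithmetic mean of the per-species amplitudes.
#' @slot referenceSpecies species with the largest observed max-minus-min.
#' @slot confirmed TRUE once the tightened re-integration reproduced period
#'   and amplitude.
#' @slot detail bookkeeping list (solver used, steps, event times).
#' @exportClass OscillationResult
setClass("OscillationResult", representation(
  period = "numeric",
  amplitudes = "numeric",
  meanAmplitude = "numeric",
  referenceSpecies = "character",
  confirmed = "logical",
  detail = "list"
))

#' Distribution summary for a sensitivity sample
#'
#' @slot n sample size.
#' @slot median sample median.
#' @slot q1,q3 first and third quartiles.
#' @slot iqr interquartile range.
#' @slot p5,p95 5th and 95th percentiles.
#' @slot range90 90\% data range, `p95 - p5`.
#' @slot medianCI 95\% notch interval of the median,
#'   `median +- 1.57 IQR / sqrt(n)`.
#' @exportClass DistributionSummary
setClass("DistributionSummary", representation(
  n = "numeric",
  median = "numeric",
  q1 = "numeric",
  q3 = "numeric",
  iqr = "numeric",
  p5 = "numeric",
  p95 = "numeric",
  range90 = "numeric",
  medianCI = "numeric"
))

#' Result of a full robustness experiment
#'
#' @slot model model name.
#' @slot records one row per accepted parameter set: period, mean amplitude,
#'   overall sensitivities `sigmaT`/`sigmaA`, and draw provenance.
#' @slot coefficients long-format per-parameter sensitivity coefficients with
#'   the perturbed period/amplitude they derive from.
#' @slot accounting sampling/discard counters (see [runAccounting()]).
#' @slot config echo of sampling interval, tolerances, perturbation size and
#'   seed.
#' @exportClass RobustnessExperiment
setClass("RobustnessExperiment", representation(
  model = "character",
  records = "data.frame",
  coefficients = "data.frame",
  accounting = "list",
  config = "list"
))
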