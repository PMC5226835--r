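# Period and amplitude sensitivity analysis by one-at-a-time perturbation.

#' Quadratic-mean overall sensitivity
#'
#' Aggregates per-parameter sensitivity coefficients into the scalar overall
#' sensitivity \eqn{\sigma = \sqrt{\frac{1}{r}\sum_l R_l^2}}.
#'
#' @param R numeric vector of sensitivity coefficients.
#' @return the quadratic mean of `R`.
#' @examples
#' overallSensitivity(c(0.3, -0.4))  # sqrt((0.09 + 0.16)/2)
#' @export
overallSensitivity <- function(R) {
  if (length(R) < 1) stop("at least one sensitivity coefficient is required")
  sqrt(mean(R^2))
}

#' Alternative overall-sensitivity definitions
#'
#' Variants of the quadratic-mean aggregation: restricted to the rate
#' coefficients only (one per flow), or to the three largest absolute
#' coefficients among all perturbable parameters.
#'
#' @param R named numeric vector of per-parameter sensitivity coefficients.
#' @param roles character vector parallel to `R`, each `"rate_coefficient"`
#'   or `"nl_parameter"`.
#' @param mode `"rate_coefficients_only"` or `"top3"`.
#' @return the alternative overall sensitivity.
#' @export
altSensitivity <- function(R, roles,
                           mode = c("rate_coefficients_only", "top3")) {
  mode <- match.arg(mode)
  if (mode == "rate_coefficients_only") {
    overallSensitivity(R[roles == "rate_coefficient"])
  } else {
    if (length(R) < 3) stop("top3 mode needs at least 3 coefficients")
    overallSensitivity(sort(abs(R), decreasing = TRUE)[1:3])
  }
}

#' Per-parameter sensitivity coefficients of period and amplitude
#'
#' Each perturbable parameter (every rate coefficient and nl-parameter;
#' never the fixed cooperativity parameters) is individually multiplied by
#' `1 + delta` and the full dynamics pipeline (probe, detection,
#' confirmation) is re-run from the unperturbed initial condition
#' `0.95 * S0`. The coefficients are
#' \eqn{R^T_l = (\Delta T/T)/(\Delta par_l/par_l)} and likewise
#' \eqn{R^A_l} for the mean amplitude. If any perturbed system fails to
#' produce a confirmed sustained oscillation the whole parameter set is
#' discarded.
#'
#' @param model a [ModelSpec-class].
#' @param set a [SampledParameterSet-class].
#' @param delta relative perturbation (default +2\%; negative values give
#'   downward perturbations).
#' @param policy an [IntegrationPolicy-class].
#' @param base confirmed unperturbed [OscillationResult-class]; computed via
#'   [simulateSet()] when omitted.
#' @return list with `status` (`"ok"` or the discard reason, prefixed
#'   `"perturbed-"` when a perturbed run failed), and for `"ok"`: named
#'   vectors `RT`, `RA`, `periodPerturbed`, `amplitudePerturbed`, plus the
#'   `base` result.
#' @export
sensitivityCoefficients <- function(model, set, delta = 0.02,
                                    policy = integrationPolicy(),
                                    base = NULL) {
  if (is.null(base)) {
    b <- simulateSet(model, set, policy)
    if (b$status != "confirmed")
      return(list(status = b$status, RT = NULL, RA = NULL))
    base <- b$result
  }
  pack <- .packModel(model)
  pert <- perturbableParameters(model)
  kn <- rateCoefficientNames(model)
  # perturbed systems inherit the solver selected for the unperturbed one
  # (a 2% parameter change does not alter the stiffness class)
  baseMethod <- if (!is.null(base@detail$solver))
    match(base@detail$solver, c("rk45", "rosenbrock")) - 1L else NULL
  RT <- RA <- pT <- pA <- stats::setNames(numeric(length(pert)), pert)
  S0 <- unname(set@S0)
  for (l in seq_along(pert)) {
    k <- unname(set@k)
    theta <- unname(set@theta)
    pn <- pert[l]
    ki <- match(pn, kn)
    if (!is.na(ki)) k[ki] <- k[ki] * (1 + delta)
    else {
      ti <- match(pn, model@nlParameters$name)
      theta[ti] <- theta[ti] * (1 + delta)
    }
    r <- .simulateParams(model, pack, k, theta, S0, policy,
                         periodGuess = base@period, method = baseMethod,
                         confirmPeriods = policy@perturbedConfirmHorizon)
    if (r$status != "confirmed")
      return(list(status = paste0("perturbed-", r$status),
                  parameter = pn, RT = NULL, RA = NULL))
    pT[l] <- r$result@period
    pA[l] <- r$result@meanAmplitude
    RT[l] <- (pT[l] / base@period - 1) / delta
    RA[l] <- (pA[l] / base@meanAmplitude - 1) / delta
  }
  list(status = "ok", RT = RT, RA = RA, periodPerturbed = pT,
       amplitudePerturbed = pA, base = base)
}

#' Full sensitivity analysis of one sampled parameter set
#'
#' Composes stability screening, the dynamics pipeline and the perturbation
#' analysis for a single sampled state and returns one sensitivity record.
#'
#' @inheritParams sensitivityCoefficients
#' @return list with `status` and, when accepted, `record` (a one-row
#'   data.frame with period, mean amplitude, `sigmaT`, `sigmaA`) and
#'   `coefficients` (long-format per-parameter table).
#' @export
analyzeSet <- function(model, set, delta = 0.02,
                       policy = integrationPolicy()) {
  stab <- classifySteadyState(model, set)
  if (stab@classification != "unstable")
    return(list(status = "stable"))
  sim <- simulateSet(model, set, policy)
  if (sim$status != "confirmed")
    return(list(status = sim$status))
  sens <- sensitivityCoefficients(model, set, delta, policy,
                                  base = sim$result)
  if (sens$status != "ok")
    return(list(status = sens$status))
  pert <- perturbableParameters(model)
  roles <- ifelse(pert %in% rateCoefficientNames(model),
                  "rate_coefficient", "nl_parameter")
  record <- data.frame(
    drawIndex = set@drawIndex,
    period = sim$result@period,
    amplitude = sim$result@meanAmplitude,
    sigmaT = overallSensitivity(sens$RT),
    sigmaA = overallSensitivity(sens$RA))
  coefficients <- data.frame(
    drawIndex = set@drawIndex,
    parameter = pert,
    role = roles,
    RT = unname(sens$RT),
    RA = unname(sens$RA),
    periodPerturbed = unname(sens$periodPerturbed),
    amplitudePerturbed = unname(sens$amplitudePerturbed))
  list(status = "accepted", record = record, coefficients = coefficients,
       oscillation = sim$result)
}
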