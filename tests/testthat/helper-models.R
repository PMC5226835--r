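# Small fixture models and independent (pure R) evaluation oracles.

# one species, constant production and linear degradation
simpleModel <- function() {
  modelSpec(
    name = "prod_deg",
    species = "S1",
    stoichiometry = matrix(c(1L, -1L), 1, 2),
    flows = list(
      flowLaw("k1"),
      flowLaw("k2", list(list(type = "power", species = "S1",
                              exponent = 1)))))
}

# independent R-level evaluation of the flow laws straight from the S4
# model description (no packing, no compiled code)
rEvalFlows <- function(model, S, params) {
  S <- stats::setNames(as.numeric(S), speciesNames(model))
  coop <- cooperativity(model)
  val <- function(x) {
    if (is.character(x)) {
      if (x %in% names(coop)) unname(coop[x]) else unname(params[x])
    } else as.numeric(x)
  }
  vapply(flowLaws(model), function(f) {
    g <- 1
    for (fc in f@factors) {
      g <- g * switch(fc$type,
        power = S[[fc$species]]^val(if (is.null(fc$exponent)) 1 else fc$exponent),
        michaelis_menten = S[[fc$species]] /
          (S[[fc$species]] + params[[fc$km]]),
        hill_activation = {
          xn <- (S[[fc$species]] / params[[fc$constant]])^val(fc$exponent)
          xn / (1 + xn)
        },
        hill_inhibition = {
          xn <- (S[[fc$species]] / params[[fc$constant]])^val(fc$exponent)
          1 / (1 + xn)
        },
        hill_basal_activation = {
          1 + (S[[fc$species]] / params[[fc$constant]])^val(fc$exponent)
        },
        transcription_switch = {
          u <- (S[[fc$inhibitor]] / params[[fc$inhibitionConstant]])^val(fc$exponent)
          num <- S[[fc$activator]] + val(fc$basal)
          num / (params[[fc$constant]] * (1 + u) + num)
        },
        stop("unknown factor type"))
    }
    unname(params[f@rateCoefficient] * g)
  }, numeric(1))
}

rEvalRHS <- function(model, S, params) {
  as.numeric(stoichiometry(model) %*% rEvalFlows(model, S, params))
}

# central finite-difference Jacobian oracle built on modelRHS
fdJacobian <- function(model, S, params, relStep = 1e-6) {
  m <- length(S)
  J <- matrix(0, m, m)
  for (j in seq_len(m)) {
    h <- relStep * abs(S[j])
    up <- dn <- S
    up[j] <- S[j] + h
    dn[j] <- S[j] - h
    J[, j] <- (modelRHS(model, up, params) - modelRHS(model, dn, params)) /
      (2 * h)
  }
  J
}

# random full parameter vector for a model
randomParams <- function(model, lo = 0.1, hi = 10) {
  pn <- perturbableParameters(model)
  stats::setNames(exp(runif(length(pn), log(lo), log(hi))), pn)
}

# deSolve right-hand side built from the independent R evaluator
deSolveFunc <- function(model, params) {
  function(t, S, p) list(rEvalRHS(model, S, params))
}
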