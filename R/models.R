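# Model construction, accessors, and evaluation of the ODE right-hand side.

flowLaw <- function(rateCoefficient, factors = list(), regulators = character(0)) {
  new("FlowLaw", rateCoefficient = rateCoefficient, factors = factors,
      regulators = regulators)
}

#' Construct a declarative oscillator model
#'
#' Low-level constructor; most users will call [chainModel()],
#' [calciumModel()], [circadianModel()] or [readModelYAML()] instead.
#'
#' @param name model identifier.
#' @param species character vector of species names, or a data.frame with
#'   columns `name` and `domain`.
#' @param stoichiometry species-by-flows integer matrix.
#' @param flows list of `FlowLaw` objects.
#' @param nlParameters data.frame with columns `name`, `role`, or a character
#'   vector of names (role defaults to `"regulation"`).
#' @param cooperativity named numeric vector of fixed parameters.
#' @param moieties list of conservation relations.
#' @param referenceParameters,referenceState optional published parameter set
#'   and matching initial state.
#' @return a validated [ModelSpec-class] object.
#' @export
modelSpec <- function(name, species, stoichiometry, flows,
                      nlParameters = data.frame(name = character(0),
                                                role = character(0)),
                      cooperativity = numeric(0),
                      moieties = list(),
                      referenceParameters = numeric(0),
                      referenceState = numeric(0)) {
  if (is.character(species))
    species <- data.frame(name = species, domain = "concentration")
  if (is.character(nlParameters))
    nlParameters <- data.frame(name = nlParameters, role = "regulation")
  stoichiometry <- as.matrix(stoichiometry)
  rownames(stoichiometry) <- species$name
  obj <- new("ModelSpec", name = name, species = species,
             stoichiometry = stoichiometry, flows = flows,
             nlParameters = nlParameters, cooperativity = cooperativity,
             moieties = moieties,
             referenceParameters = referenceParameters,
             referenceState = referenceState)
  validObject(obj)
  obj
}

#' @rdname nSpecies
#' @aliases nSpecies,ModelSpec-method
setMethod("nSpecies", "ModelSpec", function(object) nrow(object@stoichiometry))

setMethod("nFlows", "ModelSpec", function(object) ncol(object@stoichiometry))

setMethod("speciesNames", "ModelSpec", function(object) object@species$name)

setMethod("stoichiometry", "ModelSpec", function(object) object@stoichiometry)

setMethod("flowLaws", "ModelSpec", function(object) object@flows)

setMethod("nlParameters", "ModelSpec", function(object) object@nlParameters)

setMethod("cooperativity", "ModelSpec", function(object) object@cooperativity)

setMethod("rateCoefficientNames", "ModelSpec", function(object)
  vapply(object@flows, function(f) f@rateCoefficient, character(1)))

setMethod("perturbableParameters", "ModelSpec", function(object)
  c(rateCoefficientNames(object), object@nlParameters$name))

setMethod("referenceParameters", "ModelSpec",
          function(object) object@referenceParameters)

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@name, "\n")
  cat(sprintf("  %d species, %d flows, rank %d\n", nSpecies(object),
              nFlows(object), qr(object@stoichiometry)$rank))
  cat(sprintf("  perturbable parameters (%d): %s\n",
              length(perturbableParameters(object)),
              paste(perturbableParameters(object), collapse = ", ")))
  if (length(object@cooperativity))
    cat("  fixed cooperativity:",
        paste(names(object@cooperativity), object@cooperativity,
              sep = "=", collapse = ", "), "\n")
  if (length(object@moieties))
    cat("  conserved moieties:", length(object@moieties), "\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# Packing a ModelSpec for the compiled engine
# ---------------------------------------------------------------------------

.facType <- c(power = 1, michaelis_menten = 2, hill_activation = 3,
              hill_inhibition = 4, transcription_switch = 5,
              hill_basal_activation = 6)

.resolveCoop <- function(x, coop) {
  if (is.character(x)) {
    if (!x %in% names(coop))
      stop("unknown cooperativity parameter: ", x)
    unname(coop[x])
  } else as.numeric(x)
}

.packModel <- function(model) {
  sp <- speciesNames(model)
  nl <- model@nlParameters$name
  coop <- model@cooperativity
  sidx <- function(s) match(s, sp) - 1L
  tidx <- function(p) {
    i <- match(p, nl)
    if (is.na(i)) stop("unknown nl-parameter: ", p)
    i - 1L
  }
  recs <- lapply(model@flows, function(f) {
    do.call(c, c(list(length(f@factors)), lapply(f@factors, function(fc) {
      type <- .facType[[fc$type]]
      rec <- c(type, -1, -1, -1, -1, 0, 0)
      if (fc$type == "power") {
        rec[2] <- sidx(fc$species)
        rec[6] <- .resolveCoop(if (is.null(fc$exponent)) 1 else fc$exponent, coop)
      } else if (fc$type == "michaelis_menten") {
        rec[2] <- sidx(fc$species)
        rec[4] <- tidx(fc$km)
      } else if (fc$type %in% c("hill_activation", "hill_inhibition",
                                "hill_basal_activation")) {
        rec[2] <- sidx(fc$species)
        rec[4] <- tidx(fc$constant)
        rec[6] <- .resolveCoop(fc$exponent, coop)
      } else if (fc$type == "transcription_switch") {
        rec[2] <- sidx(fc$activator)
        rec[3] <- sidx(fc$inhibitor)
        rec[4] <- tidx(fc$constant)
        rec[5] <- tidx(fc$inhibitionConstant)
        rec[6] <- .resolveCoop(fc$basal, coop)
        rec[7] <- .resolveCoop(fc$exponent, coop)
      } else stop("unknown factor type: ", fc$type)
      rec
    })))
  })
  c(nSpecies(model), nFlows(model), length(nl),
    as.numeric(model@stoichiometry), unlist(recs))
}

.splitParams <- function(model, params) {
  kn <- rateCoefficientNames(model)
  nl <- model@nlParameters$name
  missing <- setdiff(c(kn, nl), names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  list(k = unname(params[kn]),
       theta = if (length(nl)) unname(params[nl]) else numeric(0))
}

# ---------------------------------------------------------------------------
# Evaluation
# ---------------------------------------------------------------------------

#' Evaluate flows, time derivatives, and the Jacobian of a model
#'
#' `modelFlows()` evaluates all flow laws \eqn{\nu_j = k_j g_j(S,\theta)};
#' `modelRHS()` returns the time derivatives \eqn{\eta \nu}; and
#' `modelJacobian()` returns the analytic Jacobian
#' \eqn{\partial(dS_i/dt)/\partial S_j} used for linear stability screening.
#'
#' @param model a [ModelSpec-class].
#' @param S strictly positive named or ordered concentration vector.
#' @param params named parameter vector containing every rate coefficient and
#'   nl-parameter of the model (cooperativity parameters are fixed in the
#'   model itself).
#' @return `modelFlows()` a named flow vector; `modelRHS()` a named derivative
#'   vector; `modelJacobian()` an m-by-m matrix.
#' @examples
#' mod <- chainModel("negative")
#' p <- c(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1, k7 = 1, k8 = 1,
#'        kn1 = 1)
#' modelRHS(mod, c(1, 1, 1, 1), p)
#' @export
modelRHS <- function(model, S, params) {
  .checkState(model, S)
  pp <- .splitParams(model, params)
  out <- cppRHS(.packModel(model), as.numeric(S), pp$k, pp$theta)
  names(out) <- speciesNames(model)
  out
}

#' @rdname modelRHS
#' @export
modelFlows <- function(model, S, params) {
  .checkState(model, S)
  pp <- .splitParams(model, params)
  out <- cppFlows(.packModel(model), as.numeric(S), pp$k, pp$theta)
  names(out) <- rateCoefficientNames(model)
  out
}

#' @rdname modelRHS
#' @export
modelJacobian <- function(model, S, params) {
  .checkState(model, S)
  pp <- .splitParams(model, params)
  J <- cppJacobian(.packModel(model), as.numeric(S), pp$k, pp$theta)
  dimnames(J) <- list(speciesNames(model), speciesNames(model))
  J
}

.checkState <- function(model, S) {
  if (length(S) != nSpecies(model))
    stop("state vector length does not match the model")
  if (any(!is.finite(S)) || any(S <= 0))
    stop("concentrations must be strictly positive")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Chain-model family
# ---------------------------------------------------------------------------

#' Build a four-species chain oscillator
#'
#' The prototype oscillator is an irreversible chain of four species S1-S4.
#' Reaction 1 produces S1 at a constant rate; reactions 2, 4, 6 are the chain
#' steps S1->S2->S3->S4; reactions 3, 5, 7, 8 degrade S1..S4. The last
#' species S4 feeds back on reaction 2 through a Hill factor
#' `fb(S4)`: `1/(1 + (S4/kn1)^n)` for negative feedback (a Goodwin-type
#' negative-feedback oscillator) or `1 + (S4/kn1)^n` for positive feedback
#' (a substrate-depletion oscillator with a basal conversion rate; the
#' basal term keeps the chain running when S4 is low, which the
#' substrate-depletion mechanism requires).
#'
#' Reactions 2-8 may individually use Michaelis-Menten instead of mass-action
#' kinetics (each saturating reaction adds a Michaelis constant `K<j>` to the
#' nl-parameters). Chain steps 2, 4, 6 may individually be turned from mass
#' conversions into regulated productions: the rate law keeps its dependence
#' on the source species but the source is no longer consumed (its -1 entry
#' is removed from the stoichiometry column). Reaction 2 of the
#' positive-feedback model must remain a conversion: substrate depletion is
#' the oscillation mechanism, and without it sustained oscillations do not
#' occur.
#'
#' @param feedback `"negative"` or `"positive"`.
#' @param kinetics `"mass_action"`, `"michaelis_menten"`, or a named
#'   character vector/list keyed by reaction index `"2"`..`"8"` for
#'   per-reaction control.
#' @param conservation `"conversion"`, `"regulated_production"`, or a named
#'   vector keyed by `"2"`, `"4"`, `"6"`.
#' @param hillN Hill coefficient `n` (fixed cooperativity parameter, never
#'   sampled or perturbed). Defaults to 9 for negative and 2 for positive
#'   feedback, the smallest integers at which sampled steady states can
#'   become unstable.
#' @return a [ModelSpec-class] with 4 species and 8 flows.
#' @examples
#' chainModel("negative")
#' chainModel("positive", kinetics = "michaelis_menten")
#' @export
chainModel <- function(feedback = c("negative", "positive"),
                       kinetics = "mass_action",
                       conservation = "conversion",
                       hillN = NULL) {
  feedback <- match.arg(feedback)
  if (is.null(hillN)) hillN <- if (feedback == "negative") 9 else 2
  if (hillN <= 0 || hillN != round(hillN))
    stop("hillN must be a positive integer")

  kin <- rep("mass_action", 7)
  names(kin) <- as.character(2:8)
  if (length(kinetics) == 1 && is.null(names(kinetics))) {
    kin[] <- match.arg(kinetics, c("mass_action", "michaelis_menten"))
  } else {
    kinetics <- unlist(kinetics)
    bad <- setdiff(names(kinetics), names(kin))
    if (length(bad))
      stop("unknown reaction index in kinetics: ", paste(bad, collapse = ", "))
    kin[names(kinetics)] <- vapply(kinetics, match.arg, character(1),
                                   c("mass_action", "michaelis_menten"))
  }

  conv <- rep("conversion", 3)
  names(conv) <- c("2", "4", "6")
  if (length(conservation) == 1 && is.null(names(conservation))) {
    conv[] <- match.arg(conservation, c("conversion", "regulated_production"))
  } else {
    conservation <- unlist(conservation)
    bad <- setdiff(names(conservation), names(conv))
    if (length(bad))
      stop("unknown reaction index in conservation: ",
           paste(bad, collapse = ", "))
    conv[names(conservation)] <-
      vapply(conservation, match.arg, character(1),
             c("conversion", "regulated_production"))
  }
  if (feedback == "positive" && conv[["2"]] == "regulated_production")
    stop("reaction 2 of the positive-feedback chain must stay a mass ",
         "conversion: the substrate-depletion mechanism requires S1 to be ",
         "consumed by the regulated step, otherwise sustained oscillations ",
         "do not occur")

  sp <- paste0("S", 1:4)
  eta <- matrix(0L, 4, 8)
  eta[1, 1] <- 1L
  src <- c(`2` = 1L, `4` = 2L, `6` = 3L)   # chain steps j: source -> source+1
  for (j in c("2", "4", "6")) {
    jc <- as.integer(j)
    if (conv[[j]] == "conversion") eta[src[[j]], jc] <- -1L
    eta[src[[j]] + 1L, jc] <- 1L
  }
  deg <- c(`3` = 1L, `5` = 2L, `7` = 3L, `8` = 4L)
  for (j in names(deg)) eta[deg[[j]], as.integer(j)] <- -1L

  nl <- data.frame(name = "kn1", role = "regulation")
  mkKinetic <- function(j, species) {
    if (kin[[as.character(j)]] == "mass_action") {
      list(rate = paste0("k", j),
           fac = list(list(type = "power", species = species, exponent = 1)))
    } else {
      km <- paste0("K", j)
      nl <<- rbind(nl, data.frame(name = km, role = "michaelis"))
      list(rate = paste0("V", j),
           fac = list(list(type = "michaelis_menten", species = species,
                           km = km)))
    }
  }
  fbFac <- list(type = if (feedback == "negative") "hill_inhibition"
                       else "hill_basal_activation",
                species = "S4", constant = "kn1", exponent = "n")

  flows <- vector("list", 8)
  flows[[1]] <- flowLaw("k1")
  for (j in c(2L, 4L, 6L)) {
    kk <- mkKinetic(j, sp[src[[as.character(j)]]])
    fac <- kk$fac
    reg <- character(0)
    if (j == 2L) {
      fac <- c(fac, list(fbFac))
      reg <- "S4"
    }
    if (conv[[as.character(j)]] == "regulated_production")
      reg <- c(sp[src[[as.character(j)]]], reg)
    flows[[j]] <- flowLaw(kk$rate, fac, regulators = reg)
  }
  for (j in names(deg)) {
    kk <- mkKinetic(as.integer(j), sp[deg[[j]]])
    flows[[as.integer(j)]] <- flowLaw(kk$rate, kk$fac)
  }
  nl <- nl[order(match(nl$name, c("kn1", paste0("K", 2:8)))), , drop = FALSE]
  rownames(nl) <- NULL

  tagKin <- if (all(kin == "mass_action")) "ma"
            else if (all(kin == "michaelis_menten")) "mm"
            else paste0("mm", paste(names(kin)[kin == "michaelis_menten"],
                                    collapse = ""))
  tagCon <- if (all(conv == "conversion")) "conv"
            else if (all(conv == "regulated_production")) "reg"
            else paste0("reg", paste(names(conv)[conv == "regulated_production"],
                                     collapse = ""))
  modelSpec(
    name = sprintf("chain_%s_%s_%s_n%d", substr(feedback, 1, 3), tagKin,
                   tagCon, hillN),
    species = sp, stoichiometry = eta, flows = flows, nlParameters = nl,
    cooperativity = c(n = hillN))
}

# ---------------------------------------------------------------------------
# Published model fixtures
# ---------------------------------------------------------------------------

#' Phenomenological calcium oscillation model
#'
#' Two-variable model of cytosolic (`Z`) and store (`Y`) calcium with
#' calcium-induced calcium release (Goldbeter, Dupont & Berridge 1990). The
#' positive feedback of cytosolic calcium on the release flow installs a
#' substrate-depletion mechanism. Flows: constant basal influx `v0`,
#' stimulus-dependent influx `v1` (the stimulation level beta is folded into
#' the published reference value), ATP-driven pumping into the store
#' (`VM2`, Hill in Z), calcium-induced release from the store (`VM3`, Hill
#' in both Y and Z), leak `kf`, and efflux `k`. Hill exponents (n = m = 2,
#' p = 4) are fixed cooperativity parameters.
#'
#' @return a [ModelSpec-class] with the published reference parameter set and
#'   starting state attached.
#' @export
calciumModel <- function() {
  eta <- matrix(0L, 2, 6)
  eta[1, 1] <- 1L                      # v0 influx
  eta[1, 2] <- 1L                      # v1 (stimulus) influx
  eta[1, 3] <- -1L; eta[2, 3] <- 1L    # pump Z -> Y
  eta[2, 4] <- -1L; eta[1, 4] <- 1L    # release Y -> Z (activated by Z)
  eta[2, 5] <- -1L; eta[1, 5] <- 1L    # leak Y -> Z
  eta[1, 6] <- -1L                     # efflux
  flows <- list(
    flowLaw("v0"),
    flowLaw("v1"),
    flowLaw("VM2", list(list(type = "hill_activation", species = "Z",
                             constant = "K2", exponent = "n"))),
    flowLaw("VM3", list(list(type = "hill_activation", species = "Y",
                             constant = "KR", exponent = "m"),
                        list(type = "hill_activation", species = "Z",
                             constant = "KA", exponent = "p")),
            regulators = "Z"),
    flowLaw("kf", list(list(type = "power", species = "Y", exponent = 1))),
    flowLaw("k", list(list(type = "power", species = "Z", exponent = 1))))
  modelSpec(
    name = "goldbeter_calcium",
    species = c("Z", "Y"),
    stoichiometry = eta,
    flows = flows,
    nlParameters = data.frame(name = c("K2", "KR", "KA"),
                              role = c("michaelis", "regulation",
                                       "regulation")),
    cooperativity = c(n = 2, m = 2, p = 4),
    referenceParameters = c(v0 = 1, v1 = 7.3 * 0.301, VM2 = 65, VM3 = 500,
                            kf = 1, k = 10, K2 = 1, KR = 2, KA = 0.9),
    referenceState = c(Z = 0.1, Y = 1.5))
}

#' Mammalian circadian oscillation model
#'
#' Seven-variable model of the mammalian circadian core loop
#' (Becker-Weimann et al. 2004): Per2/Cry mRNA (`y1`), cytosolic and nuclear
#' PER2/CRY protein (`y2`, `y3`), Bmal1 mRNA (`y4`), cytosolic, nuclear and
#' transcriptionally active BMAL1 protein (`y5`, `y6`, `y7`). Nuclear
#' PER2/CRY closes the negative feedback by shutting off Per2/Cry
#' transcription while activating Bmal1 transcription. Translation and
#' transcription steps are regulated productions (no mass flow from the
#' template species); nuclear import/export steps are conversions.
#'
#' @return a [ModelSpec-class] with the published reference parameter set and
#'   starting state attached.
#' @export
circadianModel <- function() {
  sp <- paste0("y", 1:7)
  # flows: 1 v1b (+y1), 2 k1d (-y1), 3 k2b (+y2), 4 k2d (-y2),
  # 5 k2t (y2->y3), 6 k3t (y3->y2), 7 k3d (-y3), 8 v4b (+y4), 9 k4d (-y4),
  # 10 k5b (+y5), 11 k5d (-y5), 12 k5t (y5->y6), 13 k6t (y6->y5),
  # 14 k6d (-y6), 15 k6a (y6->y7), 16 k7a (y7->y6), 17 k7d (-y7)
  eta <- matrix(0L, 7, 17)
  eta[1, 1] <- 1L; eta[1, 2] <- -1L
  eta[2, 3] <- 1L; eta[2, 4] <- -1L
  eta[2, 5] <- -1L; eta[3, 5] <- 1L
  eta[3, 6] <- -1L; eta[2, 6] <- 1L
  eta[3, 7] <- -1L
  eta[4, 8] <- 1L; eta[4, 9] <- -1L
  eta[5, 10] <- 1L; eta[5, 11] <- -1L
  eta[5, 12] <- -1L; eta[6, 12] <- 1L
  eta[6, 13] <- -1L; eta[5, 13] <- 1L
  eta[6, 14] <- -1L
  eta[6, 15] <- -1L; eta[7, 15] <- 1L
  eta[7, 16] <- -1L; eta[6, 16] <- 1L
  eta[7, 17] <- -1L
  pw <- function(s) list(list(type = "power", species = s, exponent = 1))
  flows <- list(
    flowLaw("v1b", list(list(type = "transcription_switch", activator = "y7",
                             inhibitor = "y3", constant = "k1b",
                             inhibitionConstant = "k1i", basal = "c",
                             exponent = "p")),
            regulators = c("y7", "y3")),
    flowLaw("k1d", pw("y1")),
    flowLaw("k2b", list(list(type = "power", species = "y1",
                             exponent = "q")), regulators = "y1"),
    flowLaw("k2d", pw("y2")),
    flowLaw("k2t", pw("y2")),
    flowLaw("k3t", pw("y3")),
    flowLaw("k3d", pw("y3")),
    flowLaw("v4b", list(list(type = "hill_activation", species = "y3",
                             constant = "k4b", exponent = "r")),
            regulators = "y3"),
    flowLaw("k4d", pw("y4")),
    flowLaw("k5b", list(list(type = "power", species = "y4", exponent = 1)),
            regulators = "y4"),
    flowLaw("k5d", pw("y5")),
    flowLaw("k5t", pw("y5")),
    flowLaw("k6t", pw("y6")),
    flowLaw("k6d", pw("y6")),
    flowLaw("k6a", pw("y6")),
    flowLaw("k7a", pw("y7")),
    flowLaw("k7d", pw("y7")))
  modelSpec(
    name = "becker_weimann_circadian",
    species = sp,
    stoichiometry = eta,
    flows = flows,
    nlParameters = data.frame(name = c("k1b", "k1i", "k4b"),
                              role = c("michaelis", "regulation",
                                       "regulation")),
    cooperativity = c(p = 8, q = 2, r = 3, c = 0.01),
    referenceParameters = c(v1b = 9, k1d = 0.12, k2b = 0.3, k2d = 0.05,
                            k2t = 0.24, k3t = 0.02, k3d = 0.12, v4b = 3.6,
                            k4d = 0.75, k5b = 0.24, k5d = 0.06, k5t = 0.45,
                            k6t = 0.06, k6d = 0.12, k6a = 0.09, k7a = 0.003,
                            k7d = 0.09, k1b = 1, k1i = 0.56, k4b = 2.16),
    referenceState = c(y1 = 0.2, y2 = 0.1, y3 = 1.4, y4 = 2.4, y5 = 0.3,
                       y6 = 0.2, y7 = 0.1))
}

#' Published oscillator model fixtures
#'
#' @return named list with the phenomenological calcium model
#'   (`goldbeter_calcium`) and the mammalian circadian model
#'   (`becker_weimann_circadian`).
#' @export
fixtureModels <- function() {
  list(goldbeter_calcium = calciumModel(),
       becker_weimann_circadian = circadianModel())
}
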