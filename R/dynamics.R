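# Numerical integration, oscillation detection, and the confirmation pass.

#' Integration and detection policy
#'
#' @param rtol,atol relative/absolute integration error tolerances of the
#'   detection pass (the confirmation pass divides both by 100).
#' @param probeSteps both solvers are probed with this fixed computation
#'   budget (accepted steps); the one reaching further in model time (ties
#'   broken by fewer derivative evaluations) continues.
#' @param maxTime integration horizon after which a run without a detected
#'   regular oscillation is classified not-regular.
#' @param maxSteps deterministic per-run budget of accepted solver steps,
#'   used instead of a wall-clock cap so runs are reproducible across
#'   machines.
#' @param relMaxPrecision five consecutive maxima of the reference species
#'   must agree within this relative precision.
#' @param relIntervalPrecision the four inter-maximum intervals must agree
#'   within this relative precision.
#' @param confirmAgreement maximal relative difference in period and mean
#'   amplitude between detection and confirmation pass.
#' @param confirmHorizon confirmation length for the unperturbed system, in
#'   periods.
#' @param perturbedConfirmHorizon confirmation length for perturbed systems,
#'   in periods; shorter because the unperturbed pass has already
#'   established the limit cycle and the perturbed cycle is an order-delta
#'   deformation of it.
#' @return an [IntegrationPolicy-class].
#' @export
integrationPolicy <- function(rtol = 1e-6, atol = 1e-8, probeSteps = 10000,
                              maxTime = 20000, maxSteps = 3e5,
                              relMaxPrecision = 1e-6,
                              relIntervalPrecision = 1e-4,
                              confirmAgreement = 1e-3,
                              confirmHorizon = 100,
                              perturbedConfirmHorizon = 10) {
  stopifnot(rtol > 0, atol > 0, maxTime > 0, probeSteps >= 1,
            confirmHorizon >= 5, perturbedConfirmHorizon >= 5)
  new("IntegrationPolicy", rtol = rtol, atol = atol,
      probeSteps = probeSteps, maxTime = maxTime, maxSteps = maxSteps,
      relMaxPrecision = relMaxPrecision,
      relIntervalPrecision = relIntervalPrecision,
      confirmAgreement = confirmAgreement,
      confirmHorizon = confirmHorizon,
      perturbedConfirmHorizon = perturbedConfirmHorizon)
}

.simRun <- function(pack, k, theta, y0, t0, tend, rtol, atol, method,
                    maxSteps, tout = numeric(0), bufSize = 16384L,
                    maxEvents = 200000L) {
  cppSimulate(pack, k, theta, y0, t0, tend, rtol, atol, as.integer(method),
              maxSteps, -1, as.integer(bufSize), as.integer(maxEvents),
              as.numeric(tout))
}

#' Integrate a model over a time grid
#'
#' Integrates the model ODEs and returns the solution interpolated on the
#' requested output times. With `method = "auto"` both the non-stiff
#' (Dormand-Prince RK45) and the stiff (Rosenbrock 4(3)) solver are probed
#' with an equal step budget and the one that reaches further in model time
#' continues.
#'
#' @param model a [ModelSpec-class].
#' @param params full named parameter vector (rate coefficients and
#'   nl-parameters).
#' @param y0 initial state.
#' @param times strictly increasing output time grid starting at the initial
#'   time.
#' @param method `"auto"`, `"rk45"`, or `"rosenbrock"`.
#' @param policy an [IntegrationPolicy-class].
#' @return matrix with column `time` followed by one column per species.
#' @examples
#' mod <- chainModel("negative")
#' p <- setNames(rep(1, 9), perturbableParameters(mod))
#' tr <- integrateModel(mod, p, c(1, 1, 1, 1), seq(0, 5, 0.1))
#' @export
integrateModel <- function(model, params, y0, times,
                           method = c("auto", "rk45", "rosenbrock"),
                           policy = integrationPolicy()) {
  method <- match.arg(method)
  pp <- .splitParams(model, params)
  pack <- .packModel(model)
  t0 <- times[1]
  tend <- times[length(times)]
  meth <- switch(method, rk45 = 0L, rosenbrock = 1L, auto = {
    pr <- .probeSolvers(pack, pp$k, pp$theta, as.numeric(y0), t0, tend,
                        policy@rtol, policy@atol, policy@probeSteps)
    pr$method
  })
  run <- .simRun(pack, pp$k, pp$theta, as.numeric(y0), t0, tend,
                 policy@rtol, policy@atol, meth, policy@maxSteps,
                 tout = as.numeric(times))
  if (run$status == 2)
    stop("integration failed (step size underflow) at t = ", run$t)
  out <- cbind(time = as.numeric(times), t(run$dense))
  colnames(out) <- c("time", speciesNames(model))
  out
}

# Dual-solver probe: both solvers get the same fixed computation budget
# (accepted steps, a deterministic work proxy) and the one that advances
# further in model time continues. Ties are broken by fewer derivative
# evaluations. This selects the stiff solver exactly where it pays off.
.probeSolvers <- function(pack, k, theta, y0, t0, tend, rtol, atol,
                          probeSteps = 10000) {
  p0 <- .simRun(pack, k, theta, y0, t0, tend, rtol, atol, 0L, probeSteps)
  p1 <- .simRun(pack, k, theta, y0, t0, tend, rtol, atol, 1L, probeSteps)
  pick <- if (p0$t > p1$t) 0L else if (p1$t > p0$t) 1L
          else if (p0$fevals <= p1$fevals) 0L else 1L
  run <- if (pick == 0L) p0 else p1
  list(method = pick, run = run,
       failed = (run$t <= t0 + 1e-12 * (tend - t0)) && run$status == 2)
}

# ---------------------------------------------------------------------------
# Regular-oscillation criterion
# ---------------------------------------------------------------------------

# Scan maxima (times, values) for a window of 5 consecutive maxima equal
# within relMax whose 4 intervals are equal within relInt. Scans forward by
# default (the first qualifying window, as integration would stop there);
# with fromEnd = TRUE it returns the latest qualifying window instead, and
# minTEnd requires the final period [tEnd - T, tEnd] to start after minTEnd
# (so amplitudes can be computed from the recorded step buffer).
.findRegularWindow <- function(times, values, relMax, relInt,
                               fromEnd = FALSE, minTEnd = -Inf) {
  nmax <- length(times)
  if (nmax < 5) return(NULL)
  idx <- if (fromEnd) nmax:5 else 5:nmax
  for (i in idx) {
    v <- values[(i - 4):i]
    mv <- mean(abs(v))
    if (mv == 0) next
    if ((max(v) - min(v)) / mv > relMax) next
    d <- diff(times[(i - 4):i])
    md <- mean(d)
    if (md <= 0) next
    if ((max(d) - min(d)) / md > relInt) next
    if (times[i] - md < minTEnd) next
    return(list(index = i, period = md, tEnd = times[i]))
  }
  NULL
}

# Per-species amplitudes (max - min) over [tEnd - period, tEnd] from
# recorded extrema and the step buffer.
.amplitudesFromRun <- function(m, events, bufT, bufY, tEnd, period) {
  t0 <- tEnd - period
  amp <- numeric(m)
  inBuf <- bufT >= t0 & bufT <= tEnd
  for (i in seq_len(m)) {
    sel <- events$species == i & events$time >= t0 & events$time <= tEnd
    vals <- events$value[sel]
    if (any(inBuf)) vals <- c(vals, bufY[i, inBuf])
    amp[i] <- if (length(vals)) max(vals) - min(vals) else 0
  }
  amp
}

# as .amplitudesFromRun, but from per-species extremum streams
.amplitudesFromEvents <- function(m, maxT, maxV, minT, minV, bufT, bufY,
                                  tEnd, period) {
  t0 <- tEnd - period
  amp <- numeric(m)
  inBuf <- bufT >= t0 & bufT <= tEnd
  for (i in seq_len(m)) {
    vals <- c(maxV[[i]][maxT[[i]] >= t0 & maxT[[i]] <= tEnd],
              minV[[i]][minT[[i]] >= t0 & minT[[i]] <= tEnd])
    if (any(inBuf)) vals <- c(vals, bufY[i, inBuf])
    amp[i] <- if (length(vals)) max(vals) - min(vals) else 0
  }
  amp
}

#' Detect a regular oscillation in a trajectory
#'
#' A solution counts as a regular oscillation when the species with the
#' largest observed max-minus-min (the reference species) shows five
#' consecutive maxima that are equal within `relMaxPrecision` and whose four
#' inter-maximum intervals are equal within `relIntervalPrecision`. The
#' period is the mean inter-maximum interval; per-species amplitudes are the
#' max-minus-min over the final period, and the reported amplitude is their
#' arithmetic mean. Maxima are located from the trajectory grid by sign
#' change of the discrete derivative with local quadratic refinement.
#'
#' @param trajectory matrix as returned by [integrateModel()] (column `time`
#'   then one column per species), or a plain matrix whose first column is
#'   time.
#' @param relMaxPrecision,relIntervalPrecision detection precisions.
#' @return an [OscillationResult-class] (with `confirmed = FALSE`), or `NULL`
#'   when the trajectory contains no regular oscillation.
#' @examples
#' t <- seq(0, 60, 0.01)
#' tr <- cbind(time = t, a = 2 + sin(2 * pi * t / 5), b = rep(1, length(t)))
#' detectOscillation(tr)
#' @export
detectOscillation <- function(trajectory, relMaxPrecision = 1e-6,
                              relIntervalPrecision = 1e-4) {
  tt <- trajectory[, 1]
  Y <- as.matrix(trajectory[, -1, drop = FALSE])
  m <- ncol(Y)
  spn <- colnames(Y)
  if (is.null(spn)) spn <- paste0("S", seq_len(m))
  ex <- .gridExtrema(tt, Y)
  rng <- apply(Y, 2, function(c) diff(range(c)))
  ref <- which.max(rng)
  sel <- ex$species == ref & ex$isMax
  win <- .findRegularWindow(ex$time[sel], ex$value[sel],
                            relMaxPrecision, relIntervalPrecision)
  if (is.null(win)) return(NULL)
  amp <- numeric(m)
  t0 <- win$tEnd - win$period
  inW <- tt >= t0 & tt <= win$tEnd
  for (i in seq_len(m)) {
    vals <- Y[inW, i]
    selE <- ex$species == i & ex$time >= t0 & ex$time <= win$tEnd
    vals <- c(vals, ex$value[selE])
    amp[i] <- max(vals) - min(vals)
  }
  names(amp) <- spn
  new("OscillationResult", period = win$period, amplitudes = amp,
      meanAmplitude = mean(amp), referenceSpecies = spn[ref],
      confirmed = FALSE,
      detail = list(tEnd = win$tEnd, source = "trajectory"))
}

# local extrema of gridded trajectories, refined by a quadratic through the
# three bracketing points (supports non-uniform grids)
.gridExtrema <- function(tt, Y) {
  out <- list(species = integer(0), time = numeric(0), value = numeric(0),
              isMax = logical(0))
  for (i in seq_len(ncol(Y))) {
    v <- Y[, i]
    dv <- diff(v)
    s <- sign(dv)
    idx <- which(s[-length(s)] > 0 & s[-1] <= 0) + 1L  # maxima
    idn <- which(s[-length(s)] < 0 & s[-1] >= 0) + 1L  # minima
    for (set in list(list(ix = idx, mx = TRUE), list(ix = idn, mx = FALSE))) {
      for (j in set$ix) {
        t3 <- tt[(j - 1):(j + 1)]
        v3 <- v[(j - 1):(j + 1)]
        fit <- .quadVertex(t3, v3)
        out$species <- c(out$species, i)
        out$time <- c(out$time, fit[1])
        out$value <- c(out$value, fit[2])
        out$isMax <- c(out$isMax, set$mx)
      }
    }
  }
  ord <- order(out$time)
  lapply(out, `[`, ord)
}

.quadVertex <- function(t3, v3) {
  # vertex of the parabola through three points
  d1 <- (v3[2] - v3[1]) / (t3[2] - t3[1])
  d2 <- (v3[3] - v3[2]) / (t3[3] - t3[2])
  a <- (d2 - d1) / (t3[3] - t3[1])
  if (a == 0) return(c(t3[2], v3[2]))
  tv <- (t3[1] + t3[2]) / 2 - d1 / (2 * a)
  if (tv < t3[1] || tv > t3[3]) return(c(t3[2], v3[2]))
  vv <- v3[2] + a * (tv - t3[1]) * (tv - t3[2]) +
    d1 * (tv - t3[2]) - 0  # value via Newton form through points 1,2
  # Newton form: v(t) = v1 + d1 (t - t1) + a (t - t1)(t - t2)
  vv <- v3[1] + d1 * (tv - t3[1]) + a * (tv - t3[1]) * (tv - t3[2])
  c(tv, vv)
}

setMethod("show", "OscillationResult", function(object) {
  cat(sprintf("OscillationResult: T = %.6g, A = %.6g (%s)\n",
              object@period, object@meanAmplitude,
              if (object@confirmed) "confirmed" else "preliminary"))
  cat("  reference species:", object@referenceSpecies, "\n")
  cat("  amplitudes:", paste(signif(object@amplitudes, 4), collapse = " "),
      "\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# Full per-set dynamics pipeline
# ---------------------------------------------------------------------------

# initial condition: 0.95 * S0, with conserved-moiety totals restored by
# solving the last species of each moiety from its conservation relation
.initialCondition <- function(model, S0) {
  y0 <- 0.95 * S0
  for (mo in model@moieties) {
    ix <- match(mo$species, speciesNames(model))
    tot <- sum(S0[ix])
    last <- ix[length(ix)]
    y0[last] <- tot - sum(y0[ix[-length(ix)]])
    if (y0[last] <= 0) y0[last] <- 0.05 * S0[last]
  }
  y0
}

#' Simulate a sampled parameter set and extract a confirmed oscillation
#'
#' Runs the full dynamics pipeline for one sampled steady-state parameter
#' set: integration starts at `0.95 * S0`; both solvers are probed with an
#' equal step budget and the one reaching further continues; the solution is
#' extended in
#' windows until the regular-oscillation criterion is met (five equal
#' consecutive maxima with equal intervals) or the time/step budget runs
#' out; a detected oscillation is then re-integrated from the endpoint at
#' 100-fold tightened tolerances over 100 periods, and accepted only when
#' period and mean amplitude of both passes agree within
#' `policy@confirmAgreement`. The confirmed result carries the precise
#' (tightened-tolerance) values.
#'
#' @param model a [ModelSpec-class].
#' @param set a [SampledParameterSet-class] (or any object with named `k`
#'   and `theta` obtainable via [parameterVector()]).
#' @param policy an [IntegrationPolicy-class].
#' @param periodGuess optional initial period estimate; by default the
#'   imaginary part of the leading unstable Jacobian eigenvalue sets the
#'   detection window scale.
#' @return list with `status` (`"confirmed"`, `"not-regular"`,
#'   `"confirm-mismatch"`, or `"solver-failure"`) and `result` (an
#'   [OscillationResult-class] for `"confirmed"`, otherwise `NULL`).
#' @export
simulateSet <- function(model, set, policy = integrationPolicy(),
                        periodGuess = NULL) {
  pack <- .packModel(model)
  k <- unname(set@k)
  theta <- unname(set@theta)
  .simulateParams(model, pack, k, theta, unname(set@S0), policy, periodGuess)
}

.periodGuessFromJacobian <- function(pack, k, theta, S0, nExclude = 0) {
  mr <- tryCatch({
    ev <- as.complex(cppEigvals(pack, S0, k, theta))
    if (nExclude > 0) ev <- ev[order(Mod(ev))][-seq_len(nExclude)]
    lead <- ev[which.max(Re(ev))]
    om <- abs(Im(lead))
    if (om > 0) 2 * pi / om else 1 / max(abs(Re(lead)), 1e-12)
  }, error = function(e) NA_real_)
  if (!is.finite(mr) || mr <= 0) mr <- 1
  mr
}

.EVENT_KEEP <- 3000L   # retained recent extrema per species and kind

.simulateParams <- function(model, pack, k, theta, S0, policy,
                            periodGuess = NULL, method = NULL,
                            confirmPeriods = policy@confirmHorizon) {
  m <- nSpecies(model)
  y0 <- .initialCondition(model, S0)
  if (any(y0 <= 0)) return(list(status = "solver-failure", result = NULL))
  Tg <- if (is.null(periodGuess))
    .periodGuessFromJacobian(pack, k, theta, S0, length(model@moieties))
  else periodGuess

  if (is.null(method)) {
    pr <- .probeSolvers(pack, k, theta, y0, 0, policy@maxTime,
                        policy@rtol, policy@atol, policy@probeSteps)
    if (pr$failed) return(list(status = "solver-failure", result = NULL))
    meth <- pr$method
    run <- pr$run
  } else {
    meth <- method
    run <- .simRun(pack, k, theta, y0, 0, policy@maxTime, policy@rtol,
                   policy@atol, meth, policy@probeSteps)
    if (run$status == 2 && run$t <= 1e-12 * policy@maxTime)
      return(list(status = "solver-failure", result = NULL))
  }

  # per-species extremum streams (times/values of maxima and minima);
  # detection is incremental: each round only scans windows of 5 maxima
  # ending in newly recorded ones, which matches online detection during
  # integration and keeps the scan linear in the events produced
  maxT <- maxV <- minT <- minV <- rep(list(numeric(0)), m)
  scanned <- integer(m)
  ymin <- rep(Inf, m)
  ymax <- rep(-Inf, m)
  t <- 0
  steps <- 0
  checked <- 0L

  repeat {
    sp <- run$extSpecies + 1L
    isMax <- run$extIsMax == 1L
    for (i in unique(sp)) {
      selMax <- sp == i & isMax
      selMin <- sp == i & !isMax
      if (any(selMax)) {
        maxT[[i]] <- c(maxT[[i]], run$extTime[selMax])
        maxV[[i]] <- c(maxV[[i]], run$extValue[selMax])
        if (length(maxT[[i]]) > 2L * .EVENT_KEEP) {
          drop <- length(maxT[[i]]) - .EVENT_KEEP
          maxT[[i]] <- maxT[[i]][-seq_len(drop)]
          maxV[[i]] <- maxV[[i]][-seq_len(drop)]
          scanned[i] <- max(0L, scanned[i] - drop)
        }
      }
      if (any(selMin)) {
        minT[[i]] <- c(minT[[i]], run$extTime[selMin])
        minV[[i]] <- c(minV[[i]], run$extValue[selMin])
        if (length(minT[[i]]) > 2L * .EVENT_KEEP) {
          drop <- length(minT[[i]]) - .EVENT_KEEP
          minT[[i]] <- minT[[i]][-seq_len(drop)]
          minV[[i]] <- minV[[i]][-seq_len(drop)]
        }
      }
    }
    ymin <- pmin(ymin, run$ymin)
    ymax <- pmax(ymax, run$ymax)
    t <- run$t
    y <- run$y
    steps <- steps + run$steps

    ref <- which.max(ymax - ymin)
    n <- length(maxT[[ref]])
    if (n >= 5 && scanned[ref] < n) {
      tr <- maxT[[ref]]
      vr <- maxV[[ref]]
      from <- max(scanned[ref] + 1L, 5L)
      win <- NULL
      for (i in from:n) {
        w <- .findRegularWindow(tr[(i - 4):i], vr[(i - 4):i],
                                policy@relMaxPrecision,
                                policy@relIntervalPrecision)
        if (!is.null(w)) {
          win <- w
          win$tEnd <- tr[i]
          break
        }
      }
      scanned[ref] <- n
      if (!is.null(win)) {
        amp <- .amplitudesFromEvents(m, maxT, maxV, minT, minV,
                                     run$bufT, run$bufY,
                                     win$tEnd, win$period)
        prelim <- list(period = win$period, amplitudes = amp,
                       meanAmplitude = mean(amp), ref = ref,
                       tEnd = win$tEnd)
        return(.confirmRun(model, pack, k, theta, y, t, meth, prelim,
                           policy, steps, confirmPeriods))
      }
    }
    if (run$status == 2)
      return(list(status = "solver-failure", result = NULL))
    if (t >= policy@maxTime || steps >= policy@maxSteps)
      return(list(status = "not-regular", result = NULL))
    # update the period guess from observed maxima spacing
    if (length(maxT[[ref]]) >= 3) {
      dm <- stats::median(diff(utils::tail(maxT[[ref]], 8)))
      if (is.finite(dm) && dm > 0) Tg <- dm
    } else if (checked > 0) {
      Tg <- Tg * 4   # no maxima yet: the window was too short
    }
    # persistent rejection thrash marks a problem that turned stiff after
    # the probe window; escalate to the stiff solver (one-way)
    if (meth == 0L && run$steps > 100 && run$fevals > 12 * run$steps)
      meth <- 1L
    W <- min(max(30 * Tg, .Machine$double.eps * 100), policy@maxTime - t)
    run <- .simRun(pack, k, theta, y, t, t + W, policy@rtol, policy@atol,
                   meth, policy@maxSteps - steps)
    if (run$status == 2 && run$t <= t + 1e-12 * W)
      return(list(status = "solver-failure", result = NULL))
    checked <- checked + 1L
  }
}

# confirmation pass: 100-fold tightened tolerances over 100 periods from the
# detection endpoint; precise values are the ones reported
.confirmRun <- function(model, pack, k, theta, y, t, meth, prelim, policy,
                        stepsSoFar, confirmPeriods = policy@confirmHorizon) {
  m <- nSpecies(model)
  run <- .simRun(pack, k, theta, y, t, t + confirmPeriods * prelim$period,
                 policy@rtol / 100, policy@atol / 100, meth,
                 max(policy@maxSteps, 1e6), bufSize = 8192L)
  if (run$status == 2)
    return(list(status = "solver-failure", result = NULL))
  ev <- list(species = run$extSpecies + 1L, time = run$extTime,
             value = run$extValue, isMax = run$extIsMax == 1L)
  ref <- which.max(run$ymax - run$ymin)
  sel <- ev$species == ref & ev$isMax
  # use the latest qualifying window of the precise run
  win <- .findRegularWindow(ev$time[sel], ev$value[sel],
                            policy@relMaxPrecision,
                            policy@relIntervalPrecision,
                            fromEnd = TRUE)
  if (is.null(win))
    return(list(status = "confirm-mismatch", result = NULL))
  amp <- .amplitudesFromRun(m, ev, run$bufT, run$bufY, win$tEnd, win$period)
  A <- mean(amp)
  dT <- abs(win$period - prelim$period) / win$period
  dA <- if (A > 0) abs(A - prelim$meanAmplitude) / A else Inf
  if (dT > policy@confirmAgreement || dA > policy@confirmAgreement)
    return(list(status = "confirm-mismatch", result = NULL))
  spn <- speciesNames(model)
  names(amp) <- spn
  res <- new("OscillationResult", period = win$period, amplitudes = amp,
             meanAmplitude = A, referenceSpecies = spn[ref],
             confirmed = TRUE,
             detail = list(solver = c("rk45", "rosenbrock")[meth + 1],
                           steps = stepsSoFar + run$steps,
                           prelimPeriod = prelim$period,
                           prelimAmplitude = prelim$meanAmplitude))
  list(status = "confirmed", result = res)
}
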