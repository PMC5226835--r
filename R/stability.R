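# Linear stability screening of sampled steady states.

.MARGINAL_TOL <- 1e-12

#' Classify the linear stability of a sampled steady state
#'
#' Computes the eigenvalues of the analytic Jacobian at the sampled steady
#' state. The state is unstable when at least one eigenvalue has a positive
#' real part; only unstable states can support the limit-cycle oscillations
#' this workflow looks for, so only they proceed to numerical integration.
#' Eigenvalues with `|Re| <= 1e-12` are treated as marginal and classified
#' stable (conservatively excluded from simulation). For models with
#' conserved moieties, the conservation-induced zero modes (the eigenvalues
#' of smallest modulus, one per moiety) are excluded before classification.
#'
#' @param model a [ModelSpec-class].
#' @param set a [SampledParameterSet-class].
#' @return a [StabilityResult-class].
#' @export
classifySteadyState <- function(model, set) {
  pp <- list(k = unname(set@k), theta = unname(set@theta))
  ev <- as.complex(cppEigvals(.packModel(model), unname(set@S0), pp$k,
                              pp$theta))
  nEx <- length(model@moieties)
  if (nEx > 0) {
    ord <- order(Mod(ev))
    ev <- ev[ord][-seq_len(nEx)]
  }
  mr <- max(Re(ev))
  marginal <- abs(mr) <= .MARGINAL_TOL
  new("StabilityResult", eigenvalues = ev,
      classification = if (mr > .MARGINAL_TOL) "unstable" else "stable",
      maxRealPart = mr, marginal = marginal)
}

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult:", object@classification,
      if (object@marginal) "(marginal)" else "", "\n")
  cat("  max Re(lambda):", format(object@maxRealPart), "\n")
  cat("  eigenvalues:", paste(format(object@eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  invisible(NULL)
})

# batch classification used by the pipeline: max real part per column
.maxRePartBatch <- function(pack, S0, k, theta, nExclude = 0L) {
  cppMaxReEig(pack, S0, k,
              if (nrow(theta) == 0) matrix(0, 0, ncol(S0)) else theta,
              as.integer(nExclude))
}

#' Hill-coefficient instability scan of the chain models
#'
#' For each integer Hill coefficient `n` and each ratio bin
#' `(10^a, 10^(a+0.1))`, the scan samples steady states conditioned on
#' `S4/kn1` falling inside the bin (S4 and kn1 are drawn jointly
#' log10-uniformly and accepted by rejection) and reports the percentage of
#' unstable steady states. The default bin grid follows the published scan
#' (`a = -6, -5.9, ..., 5.9` with 10,000 states per bin); `reduced = TRUE`
#' switches to a coarse desk-scale grid (`a = -3, -2.5, ..., 2.5` with 900
#' states per bin, i.e. more than 10,000 states per Hill coefficient) that still
#' brackets the `S4/kn1 ~ 1` region where instability emerges.
#'
#' @param feedback chain-model feedback type, `"negative"` or `"positive"`.
#' @param nRange integer Hill coefficients to scan.
#' @param binStarts log10 lower bin edges `a`; each bin is
#'   `(10^a, 10^(a+0.1))`.
#' @param setsPerBin states sampled per `(n, bin)` cell.
#' @param config a [SampleConfig-class].
#' @param reduced use the coarse desk-scale grid (overrides `binStarts` and
#'   `setsPerBin`).
#' @param builder optional function `n -> ModelSpec` replacing the default
#'   chain-model builder (the scanned species is always the last one, the
#'   scanned nl-parameter the first one).
#' @return long-format data.frame with columns `n`, `bin_low`, `bin_high`,
#'   `n_sampled`, `n_unstable`, `pct_unstable`.
#' @examples
#' \donttest{
#' sc <- instabilityScan("positive", nRange = 1:2, reduced = TRUE,
#'                       config = sampleConfig(seed = 1))
#' aggregate(n_unstable ~ n, sc, sum)
#' }
#' @export
instabilityScan <- function(feedback = c("negative", "positive"),
                            nRange = 1:12,
                            binStarts = seq(-6, 5.9, by = 0.1),
                            setsPerBin = 10000,
                            config = sampleConfig(),
                            reduced = FALSE,
                            builder = NULL) {
  feedback <- match.arg(feedback)
  if (reduced) {
    binStarts <- seq(-3, 2.5, by = 0.5)
    setsPerBin <- 900
  }
  if (setsPerBin < 1) stop("setsPerBin must be >= 1")
  if (is.null(builder))
    builder <- function(n) chainModel(feedback, hillN = n)
  if (!is.na(config@seed)) set.seed(config@seed)
  iv <- log10(config@interval)
  binWidth <- 0.1
  rows <- list()
  for (n in nRange) {
    model <- builder(n)
    pack <- .packModel(model)
    m <- nSpecies(model)
    b <- .speciesLogBounds(model, config)
    for (a in binStarts) {
      # rejection-sample (S_last, theta_1) pairs with log10 ratio in [a, a+0.1)
      need <- setsPerBin
      sLast <- numeric(0); th1 <- numeric(0)
      while (length(sLast) < need) {
        chunk <- max(2000, ceiling((need - length(sLast)) /
                                     max(binWidth * (iv[2] - iv[1] - abs(a)) /
                                           (iv[2] - iv[1])^2, 1e-3)))
        ls <- runif(chunk, b$lo[m], b$hi[m])
        lt <- runif(chunk, iv[1], iv[2])
        keep <- (ls - lt) >= a & (ls - lt) < a + binWidth
        sLast <- c(sLast, 10^ls[keep])
        th1 <- c(th1, 10^lt[keep])
      }
      sLast <- sLast[seq_len(need)]
      th1 <- th1[seq_len(need)]
      Sfix <- matrix(NA_real_, m, need)
      Sfix[m, ] <- sLast
      Tfix <- matrix(NA_real_, nrow(model@nlParameters), need)
      Tfix[1, ] <- th1
      st <- cppSampleStates(pack, as.integer(need), b$lo, b$hi, iv[1], iv[2],
                            iv[1], iv[2],
                            as.integer(config@maxFlowResampleAttempts),
                            Sfix, Tfix)
      ok <- st$ok
      mr <- .maxRePartBatch(pack, st$S0[, ok, drop = FALSE],
                            st$k[, ok, drop = FALSE],
                            st$theta[, ok, drop = FALSE],
                            length(model@moieties))
      nUnst <- sum(mr > .MARGINAL_TOL, na.rm = TRUE)
      nSamp <- sum(ok)
      rows[[length(rows) + 1]] <- data.frame(
        n = n, bin_low = 10^a, bin_high = 10^(a + binWidth),
        n_sampled = nSamp, n_unstable = nUnst,
        pct_unstable = 100 * nUnst / max(nSamp, 1))
    }
  }
  do.call(rbind, rows)
}

#' Smallest Hill coefficient with an unstable sampled steady state
#'
#' Convenience reduction of [instabilityScan()]: the smallest `n` in the
#' scanned range for which any sampled steady state is unstable, or `NA` if
#' none is.
#'
#' @param scan result of [instabilityScan()].
#' @return integer (or `NA`).
#' @export
instabilityThreshold <- function(scan) {
  agg <- tapply(scan$n_unstable, scan$n, sum)
  hit <- as.integer(names(agg))[agg > 0]
  if (length(hit)) min(hit) else NA_integer_
}
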