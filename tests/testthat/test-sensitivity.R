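# Sensitivity coefficients and overall sensitivities.

test_that("overall sensitivity is the quadratic mean of the coefficients", {
  expect_equal(overallSensitivity(0.5), 0.5)
  expect_equal(overallSensitivity(c(0.3, -0.4)), sqrt((0.09 + 0.16) / 2))
  expect_equal(overallSensitivity(rep(0, 9)), 0)
  expect_error(overallSensitivity(numeric(0)), "at least one")
})

test_that("alternative sensitivity measures behave as documented", {
  R <- c(a = 1, b = 0, c = 0, d = 0)
  roles <- rep("rate_coefficient", 4)
  # without nl-parameters the restricted measure equals the standard one
  expect_equal(altSensitivity(R, roles, "rate_coefficients_only"),
               overallSensitivity(R))
  expect_equal(altSensitivity(R, roles, "top3"), sqrt(1 / 3))
  expect_error(altSensitivity(c(1, 2), c("a", "b"), "top3"), "at least 3")
  # with nl-parameters the restricted measure drops them
  R2 <- c(k = 0.6, K = 100)
  roles2 <- c("rate_coefficient", "nl_parameter")
  expect_equal(altSensitivity(R2, roles2, "rate_coefficients_only"), 0.6)
  # top3 dominates the standard measure when 3 coefficients carry all mass
  R3 <- c(1, 0.9, 0.8, 0, 0, 0, 0)
  expect_gt(altSensitivity(R3, rep("rate_coefficient", 7), "top3"),
            overallSensitivity(R3))
})

test_that("one-sided coefficients match a central-difference oracle", {
  mod <- chainModel("negative")
  st <- sampleStates(mod, 60000, sampleConfig(seed = 42))
  mr <- oscrobust:::.maxRePartBatch(oscrobust:::.packModel(mod),
                                    st$S0, st$k, st$theta)
  un <- which(mr > 1e-12)
  checked <- 0
  for (i in un) {
    s <- oscrobust:::.setFromBatch(mod, st, i)
    base <- simulateSet(mod, s)
    if (base$status != "confirmed") next
    up <- sensitivityCoefficients(mod, s, delta = 0.02, base = base$result)
    if (up$status != "ok") next
    dn <- sensitivityCoefficients(mod, s, delta = -0.02, base = base$result)
    if (dn$status != "ok") next
    central <- (up$RT + dn$RT) / 2
    for (l in which(abs(central) > 0.1)) {
      expect_equal(unname(up$RT[l]), unname(central[l]), tolerance = 0.1)
    }
    checked <- checked + 1
    if (checked >= 2) break
  }
  expect_gte(checked, 1)
})

test_that("overall sensitivities are re-derivable from stored perturbed values", {
  ex <- cachedNegativeRun()
  co <- sensitivityCoefficientTable(ex)
  re <- sensitivityRecords(ex)
  for (id in re$setId[1:50]) {
    rows <- co[co$setId == id, ]
    rec <- re[re$setId == id, ]
    # provenance: recompute R and sigma from the raw perturbed T/A
    RT <- (rows$periodPerturbed / rec$period - 1) / 0.02
    RA <- (rows$amplitudePerturbed / rec$amplitude - 1) / 0.02
    expect_equal(RT, rows$RT, tolerance = 1e-12)
    expect_equal(overallSensitivity(RT), rec$sigmaT, tolerance = 1e-12)
    expect_equal(overallSensitivity(RA), rec$sigmaA, tolerance = 1e-12)
  }
})

test_that("raising a degradation rate mostly shortens the period", {
  # sign convention: in the negative-feedback chain, R^T of the degradation
  # rate coefficients is predominantly negative (majority property over the
  # accepted sets, not per set)
  ex <- cachedNegativeRun()
  co <- sensitivityCoefficientTable(ex)
  deg <- co[co$parameter %in% c("k3", "k5", "k7", "k8"), ]
  expect_gt(mean(deg$RT < 0), 0.5)
})

test_that("Michaelis constants matter less than their rate coefficients", {
  # saturating-kinetics variant: median |R| of each K_M is below the median
  # |R| of the paired maximal velocity
  ex <- cachedRun("negMM40", runExperiment(
    chainModel("negative", kinetics = "michaelis_menten"),
    targetAccepted = 40, seed = 4803))
  co <- sensitivityCoefficientTable(ex)
  medAbs <- function(p) median(abs(co$RT[co$parameter == p]))
  kmLess <- vapply(3:8, function(j)
    medAbs(paste0("K", j)) < medAbs(paste0("V", j)), logical(1))
  expect_gt(mean(kmLess), 0.5)
  medAbsA <- function(p) median(abs(co$RA[co$parameter == p]))
  kmLessA <- vapply(3:8, function(j)
    medAbsA(paste0("K", j)) < medAbsA(paste0("V", j)), logical(1))
  expect_gt(mean(kmLessA), 0.5)
})
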