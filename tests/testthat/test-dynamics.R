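# Integration, oscillation detection, and confirmation.

test_that("both solvers reproduce exponential decay to solver tolerance", {
  mod <- simpleModel()
  p <- c(k1 = 1e-12, k2 = 1)   # negligible production, dS/dt ~ -S
  tt <- seq(0, 10, 0.1)
  for (meth in c("rk45", "rosenbrock")) {
    tr <- integrateModel(mod, p, 1, tt, method = meth)
    expect_lt(max(abs(tr[, 2] - exp(-tt))), 1e-5)
  }
})

test_that("trajectories from stable sampled states converge to the steady state", {
  mod <- chainModel("negative")
  st <- sampleStates(mod, 20, sampleConfig(seed = 41))
  mr <- oscrobust:::.maxRePartBatch(oscrobust:::.packModel(mod),
                                    st$S0, st$k, st$theta)
  i <- which(mr < -0.5)[1]   # strongly stable -> fast convergence
  expect_false(is.na(i))
  s <- oscrobust:::.setFromBatch(mod, st, i)
  tr <- integrateModel(mod, parameterVector(s), 0.95 * steadyState(s),
                       seq(0, 30 / abs(mr[i]), length.out = 200))
  final <- tr[nrow(tr), -1]
  expect_lt(max(abs(final / steadyState(s) - 1)), 1e-3)
})

test_that("analytic sinusoids are detected with exact period and amplitude", {
  tt <- seq(0, 60, 0.01)
  tr <- cbind(time = tt, a = 2 + sin(2 * pi * tt / 5), b = rep(1, length(tt)))
  det <- detectOscillation(tr)
  expect_false(is.null(det))
  expect_equal(det@period, 5, tolerance = 1e-4)
  expect_equal(unname(det@amplitudes), c(2, 0), tolerance = 1e-3)
  expect_equal(det@meanAmplitude, 1, tolerance = 1e-3)
  expect_identical(det@referenceSpecies, "a")

  # damped oscillation: maxima are not equal within 1e-6
  trd <- cbind(time = tt, a = 2 + exp(-tt / 10) * sin(2 * pi * tt / 5))
  expect_null(detectOscillation(trd))
})

test_that("detection is invariant to a time-axis offset", {
  set.seed(42)
  for (rep in 1:5) {
    phase <- runif(1, 0, 5)
    tt <- seq(0, 60, 0.01)
    tr <- cbind(time = tt, a = 2 + sin(2 * pi * (tt + phase) / 5))
    det <- detectOscillation(tr)
    expect_false(is.null(det))
    expect_equal(det@period, 5, tolerance = 1e-4)
  }
})

test_that("detected periods match an independent integration oracle", {
  mod <- chainModel("negative")
  st <- sampleStates(mod, 60000, sampleConfig(seed = 42))
  mr <- oscrobust:::.maxRePartBatch(oscrobust:::.packModel(mod),
                                    st$S0, st$k, st$theta)
  un <- which(mr > 1e-12)
  checked <- 0
  for (i in un) {
    s <- oscrobust:::.setFromBatch(mod, st, i)
    r <- simulateSet(mod, s)
    if (r$status != "confirmed") next
    T0 <- r$result@period
    if (T0 > 200) next   # keep the oracle integration affordable
    # independent high-precision run: deSolve lsoda on the R-level flow
    # laws, sampled densely over a long stretch
    p <- parameterVector(s)
    dt <- T0 / 400
    out <- deSolve::lsoda(0.95 * steadyState(s), seq(0, 60 * T0, dt),
                          deSolveFunc(mod, p), NULL,
                          rtol = 1e-9, atol = 1e-11)
    tailPart <- out[out[, 1] > 40 * T0, ]
    ref <- 1 + which.max(apply(tailPart[, -1], 2,
                               function(c) diff(range(c))))
    v <- tailPart[, ref]
    tt <- tailPart[, 1]
    # quadratic-refined maxima times of the oracle trajectory
    im <- which(diff(sign(diff(v))) == -2) + 1
    tmx <- vapply(im, function(j) {
      d1 <- (v[j] - v[j - 1]) / dt
      d2 <- (v[j + 1] - v[j]) / dt
      (tt[j - 1] + tt[j]) / 2 - d1 * dt / (d2 - d1)
    }, numeric(1))
    Toracle <- median(diff(tmx))
    expect_equal(T0, Toracle, tolerance = 1e-3)
    # coarse autocorrelation cross-check (peak of the acf at one period)
    ac <- acf(v, lag.max = 600, plot = FALSE)$acf[-1]
    lag <- which(diff(sign(diff(ac))) == -2)[1] + 1
    expect_equal(T0, lag * dt, tolerance = 0.01)
    checked <- checked + 1
    if (checked >= 2) break
  }
  expect_gte(checked, 1)
})

test_that("confirmed results are insensitive to further tolerance tightening", {
  mod <- chainModel("negative")
  st <- sampleStates(mod, 60000, sampleConfig(seed = 42))
  mr <- oscrobust:::.maxRePartBatch(oscrobust:::.packModel(mod),
                                    st$S0, st$k, st$theta)
  un <- which(mr > 1e-12)
  checked <- 0
  for (i in un) {
    s <- oscrobust:::.setFromBatch(mod, st, i)
    r <- simulateSet(mod, s)
    if (r$status != "confirmed") next
    r2 <- simulateSet(mod, s, integrationPolicy(rtol = 5e-7, atol = 5e-9))
    if (r2$status != "confirmed") next
    expect_equal(r$result@period, r2$result@period, tolerance = 1e-4)
    checked <- checked + 1
    if (checked >= 2) break
  }
  expect_gte(checked, 1)
})

test_that("an exhausted budget yields a not-regular verdict", {
  mod <- chainModel("negative")
  st <- sampleStates(mod, 60000, sampleConfig(seed = 42))
  mr <- oscrobust:::.maxRePartBatch(oscrobust:::.packModel(mod),
                                    st$S0, st$k, st$theta)
  i <- which(mr > 1e-12)[1]
  s <- oscrobust:::.setFromBatch(mod, st, i)
  r <- simulateSet(mod, s, integrationPolicy(maxSteps = 200, probeSteps = 50))
  expect_true(r$status %in% c("not-regular", "solver-failure"))
})
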