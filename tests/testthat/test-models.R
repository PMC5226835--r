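# Model builders, flow-law evaluation, and Jacobians.

test_that("chain-model builder produces the documented structures", {
  neg <- chainModel("negative")
  expect_equal(nSpecies(neg), 4)
  expect_equal(nFlows(neg), 8)
  expect_equal(length(perturbableParameters(neg)), 9)
  expect_equal(cooperativity(neg), c(n = 9))

  # all Michaelis-Menten, positive feedback, n = 2: 8 rate coefficients +
  # kn1 + 7 Michaelis constants
  posMM <- chainModel("positive", kinetics = "michaelis_menten")
  expect_equal(cooperativity(posMM), c(n = 2))
  expect_equal(length(perturbableParameters(posMM)), 16)
  expect_setequal(nlParameters(posMM)$name, c("kn1", paste0("K", 2:8)))

  # regulated production removes the source entry, keeps the product entry
  reg <- chainModel("negative", conservation = "regulated_production")
  eta <- stoichiometry(reg)
  for (j in c(2, 4, 6)) {
    expect_equal(sum(eta[, j] == 1), 1)
    expect_equal(sum(eta[, j] == -1), 0)
  }
  # conversions have one source and one product; degradations one source
  etaC <- stoichiometry(neg)
  for (j in c(2, 4, 6)) {
    expect_equal(sum(etaC[, j] == 1), 1)
    expect_equal(sum(etaC[, j] == -1), 1)
  }
  for (j in c(3, 5, 7, 8)) {
    expect_equal(sum(etaC[, j] == -1), 1)
    expect_equal(sum(etaC[, j] != 0), 1)
  }
})

test_that("kinetics variants change flow laws but never the stoichiometry", {
  neg <- chainModel("negative")
  for (kin in list("michaelis_menten",
                   c(`3` = "michaelis_menten", `5` = "michaelis_menten",
                     `7` = "michaelis_menten", `8` = "michaelis_menten"),
                   c(`2` = "michaelis_menten", `4` = "michaelis_menten",
                     `6` = "michaelis_menten"))) {
    v <- chainModel("negative", kinetics = kin)
    expect_identical(stoichiometry(v), stoichiometry(neg))
  }
})

test_that("invalid chain-model requests are rejected with explanations", {
  expect_error(chainModel("positive",
                          conservation = c(`2` = "regulated_production")),
               "substrate-depletion")
  expect_error(chainModel("negative", kinetics = c(`9` = "mass_action")),
               "unknown reaction index")
  expect_error(chainModel("negative", hillN = 2.5), "positive integer")
})

test_that("balanced production and degradation give zero derivative", {
  mod <- simpleModel()
  expect_equal(modelRHS(mod, 1, c(k1 = 1, k2 = 1)), c(S1 = 0))
  expect_error(modelRHS(mod, -1, c(k1 = 1, k2 = 1)), "strictly positive")
})

test_that("compiled flow evaluation matches an independent R evaluation", {
  set.seed(11)
  models <- list(chainModel("negative", kinetics = "michaelis_menten"),
                 chainModel("positive"), calciumModel(), circadianModel())
  for (mod in models) {
    for (rep in 1:20) {
      S <- 10^runif(nSpecies(mod), -2, 2)
      p <- randomParams(mod)
      expect_equal(unname(modelFlows(mod, S, p)), rEvalFlows(mod, S, p),
                   tolerance = 1e-12)
      expect_equal(unname(modelRHS(mod, S, p)), rEvalRHS(mod, S, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("all flows are positive at random positive states", {
  set.seed(12)
  for (mod in list(chainModel("negative"),
                   chainModel("positive", kinetics = "michaelis_menten"),
                   calciumModel(), circadianModel())) {
    for (rep in 1:250) {
      S <- 10^runif(nSpecies(mod), -3, 3)
      p <- randomParams(mod)
      expect_true(all(modelFlows(mod, S, p) > 0))
    }
  }
})

test_that("analytic Jacobian agrees with a finite-difference oracle", {
  set.seed(13)
  for (mod in list(chainModel("negative"),
                   chainModel("positive", kinetics = "michaelis_menten"),
                   calciumModel(), circadianModel())) {
    for (rep in 1:5) {
      S <- 10^runif(nSpecies(mod), -1, 1)
      p <- randomParams(mod)
      J <- modelJacobian(mod, S, p)
      Jfd <- fdJacobian(mod, S, p)
      expect_equal(unname(J), unname(Jfd), tolerance = 1e-5)
    }
  }
  # pure linear degradation: Jacobian is -k2
  mod <- simpleModel()
  expect_equal(unname(modelJacobian(mod, 2, c(k1 = 3, k2 = 0.7))[1, 1]),
               -0.7, tolerance = 1e-12)
})

test_that("derivatives along an integrated trajectory match the RHS", {
  set.seed(14)
  mod <- chainModel("negative")
  st <- sampleStates(mod, 1, sampleConfig(seed = 14))
  set <- sampleState(mod, sampleConfig(seed = 14))
  p <- parameterVector(set)
  tt <- seq(0, 5, 0.002)
  tr <- integrateModel(mod, p, 0.95 * steadyState(set), tt)
  # central differences on the dense trajectory vs the analytic RHS; the
  # finite-difference truncation error spikes at sharp features, so the
  # bulk of the points must agree tightly and all within 5%
  mid <- seq(50, length(tt) - 50, by = 13)
  err <- vapply(mid, function(i) {
    fd <- (tr[i + 1, -1] - tr[i - 1, -1]) / (tt[i + 1] - tt[i - 1])
    an <- modelRHS(mod, tr[i, -1], p)
    max(abs(fd - an)) / max(abs(an), 1e-8)
  }, numeric(1))
  expect_lt(median(err), 1e-4)
  expect_lt(quantile(err, 0.9), 5e-3)
  expect_lt(max(err), 0.05)
})

test_that("published calcium model oscillates at its reference set", {
  mod <- calciumModel()
  p <- referenceParameters(mod)
  tr <- integrateModel(mod, p, mod@referenceState, seq(0, 80, 0.005))
  det <- detectOscillation(tr)
  expect_false(is.null(det))
  expect_gt(det@period, 0.5)
  expect_lt(det@period, 20)
})

test_that("model definitions round-trip through YAML", {
  mod <- chainModel("positive", kinetics = c(`2` = "michaelis_menten"))
  f <- tempfile(fileext = ".yaml")
  writeModelYAML(mod, f)
  back <- readModelYAML(f)
  expect_identical(unname(stoichiometry(back)), unname(stoichiometry(mod)))
  expect_identical(perturbableParameters(back), perturbableParameters(mod))
  expect_identical(oscrobust:::.packModel(back), oscrobust:::.packModel(mod))
  # the shipped example definition loads cleanly
  ex <- readModelYAML(system.file("extdata", "chain_negative.yaml",
                                  package = "oscrobust"))
  expect_identical(oscrobust:::.packModel(ex),
                   oscrobust:::.packModel(chainModel("negative")))
  unlink(f)
})
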