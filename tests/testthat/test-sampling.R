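# Bottom-up sampling: intervals, flow balance, back-solving.

test_that("concentration draws are log10-uniform on the interval", {
  mod <- chainModel("negative")
  cfg <- sampleConfig(seed = 21)
  S <- sampleConcentrations(mod, 25000, cfg)
  expect_true(all(S > 1e-3 & S < 1e3))
  # symmetry of log10-uniform around 1
  expect_equal(mean(S < 1), 0.5, tolerance = 0.01)
  # uniform counts across the 6 decades
  dec <- cut(log10(S), breaks = -3:3)
  p <- chisq.test(table(dec))$p.value
  expect_gt(p, 0.001)
})

test_that("probability-tagged species are drawn on the probability interval", {
  mod <- chainModel("negative")
  mod@species$domain[2] <- "probability"
  S <- sampleConcentrations(mod, 5000, sampleConfig(seed = 22))
  expect_true(all(S[2, ] > 1e-3 & S[2, ] <= 1))
  expect_gt(max(S[1, ]), 1)
})

test_that("sampled flows satisfy the steady-state condition inside the interval", {
  mod <- chainModel("negative")
  st <- sampleStates(mod, 2000, sampleConfig(seed = 23))
  expect_true(all(st$ok))
  res <- stoichiometry(mod) %*% st$nu0
  expect_lt(max(abs(res)), 1e-12 * max(st$nu0))
  expect_true(all(st$nu0 > 1e-3 & st$nu0 < 1e3))
})

test_that("a two-flow single-species model forces equal flows", {
  mod <- simpleModel()
  nu <- sampleFlows(mod, sampleConfig(seed = 24))
  expect_identical(unname(nu[1]), unname(nu[2]))
})

test_that("rate coefficients are back-solved from the flow laws", {
  # mass action: nu = k S -> k = nu / S
  mod <- simpleModel()
  k <- solveRateCoefficients(mod, S0 = 4, nu0 = c(2, 2))
  expect_equal(unname(k[2]), 0.5)
  # Michaelis-Menten: nu = V S/(S+K), S = K = 1 -> V = 2 nu
  mm <- modelSpec("mm1", "S1", matrix(c(1L, -1L), 1, 2),
                  list(flowLaw("k1"),
                       flowLaw("V2", list(list(type = "michaelis_menten",
                                               species = "S1", km = "K2")))),
                  nlParameters = data.frame(name = "K2", role = "michaelis"))
  k <- solveRateCoefficients(mm, S0 = 1, nu0 = c(1, 1), theta = c(K2 = 1))
  expect_equal(unname(k[2]), 2)
  # regulated conversion with inhibitory feedback factor 0.5 (S4 = kn1)
  neg <- chainModel("negative")
  k <- solveRateCoefficients(neg, S0 = c(2, 1, 1, 1),
                             nu0 = c(1, 1, 1, 1, 1, 1, 1, 1),
                             theta = c(kn1 = 1))
  expect_equal(unname(k[2]), 1)  # nu2 = k2 * S1 * 0.5 = k2
})

test_that("forward evaluation reproduces the sampled flows and steady state", {
  mod <- chainModel("negative", kinetics = "michaelis_menten")
  st <- sampleStates(mod, 500, sampleConfig(seed = 25))
  for (i in which(st$ok)[1:200]) {
    set <- oscrobust:::.setFromBatch(mod, st, i)
    nu <- modelFlows(mod, steadyState(set), parameterVector(set))
    expect_lt(max(abs(nu / steadyStateFlows(set) - 1)), 1e-9)
    rhs <- modelRHS(mod, steadyState(set), parameterVector(set))
    expect_lt(max(abs(rhs)), 1e-9 * max(steadyStateFlows(set)))
  }
})

test_that("sampling is deterministic under a fixed seed", {
  mod <- chainModel("positive")
  a <- sampleStates(mod, 50, sampleConfig(seed = 26))
  b <- sampleStates(mod, 50, sampleConfig(seed = 26))
  expect_identical(a$S0, b$S0)
  expect_identical(a$nu0, b$nu0)
  expect_identical(a$k, b$k)
  expect_identical(a$theta, b$theta)
})

test_that("sampled Michaelis-Menten terms have median one half", {
  mod <- chainModel("negative", kinetics = "michaelis_menten")
  st <- sampleStates(mod, 20000, sampleConfig(seed = 27))
  # pool the saturation terms of the four degradation reactions
  term <- c(st$S0["S1", ] / (st$S0["S1", ] + st$theta["K3", ]),
            st$S0["S2", ] / (st$S0["S2", ] + st$theta["K5", ]),
            st$S0["S3", ] / (st$S0["S3", ] + st$theta["K7", ]),
            st$S0["S4", ] / (st$S0["S4", ] + st$theta["K8", ]))
  expect_equal(median(term), 0.5, tolerance = 0.02)
})
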