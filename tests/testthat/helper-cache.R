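# Expensive Monte-Carlo runs computed once per test session and shared
# between test files. Each entry has its own fixed seed, so results do not
# depend on which test asks first.

.runCache <- new.env(parent = emptyenv())

cachedRun <- function(name, expr) {
  if (!exists(name, envir = .runCache)) {
    assign(name, force(expr), envir = .runCache)
  }
  get(name, envir = .runCache)
}

cachedNegativeRun <- function() {
  cachedRun("neg250", runExperiment(chainModel("negative"),
                                    targetAccepted = 250, seed = 4801))
}

cachedPositiveRun <- function() {
  cachedRun("pos250", runExperiment(chainModel("positive"),
                                    targetAccepted = 250, seed = 4802))
}
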