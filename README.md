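# oscrobust

`oscrobust` quantifies how robust the **period** and **amplitude** of
limit-cycle oscillations in ODE models of cellular processes are against
small parameter perturbations. It is aimed at systems biologists who want
to know whether robustness is a property of a model's *structure* —
feedback type, reaction kinetics, mass conservation — rather than of a
lucky choice of parameter values: circadian clocks keep near-24 h timing
under wildly varying conditions, while calcium oscillations shift
frequency readily, and the question is which design features produce which
behaviour.

## The method

A model is a positive-flow ODE system `dS/dt = η ν` with more flows than
species; every flow is linear in one rate coefficient,
`ν_j = k_j g_j(S, θ)`. The analysis pipeline:

1. **Bottom-up sampling.** Steady-state concentrations `S⁰`, balanced
   flows `ν⁰` (solving `η ν⁰ = 0` with randomly chosen free flows) and
   nonlinear parameters `θ` are drawn log10-uniformly over
   `(10⁻³, 10³)`; the rate coefficients follow uniquely as
   `k_j = ν⁰_j / g_j(S⁰, θ)`.
2. **Stability screen.** Only states whose analytic Jacobian has an
   eigenvalue with positive real part can oscillate; the rest are
   discarded without integration.
3. **Dynamics.** Unstable states are integrated (dual non-stiff/stiff
   solver with a work-based probe) until the trajectory shows a *regular
   oscillation*: five consecutive maxima equal within 10⁻⁶ with
   inter-maximum intervals equal within 10⁻⁴. Detections are confirmed by
   re-integration at 100-fold tightened tolerances over 100 periods.
4. **Sensitivity.** Each perturbable parameter `par_l` (rate coefficients
   and nl-parameters, never Hill exponents) is raised by 2% and the
   pipeline re-run. The coefficients `R^T_l = (ΔT/T)/(Δpar_l/par_l)` and
   `R^A_l` (for the mean of the per-species amplitudes) aggregate into the
   overall sensitivities

   σ_T = sqrt( (1/r) Σ_l (R^T_l)² ),  σ_A analogously,

   and a parameter set is *accepted* only when the unperturbed system and
   all `r` perturbed systems yield confirmed sustained oscillations.
5. **Statistics.** Medians, quartiles and the 90% data range (5th–95th
   percentile distance) summarise the σ distributions over thousands of
   accepted sets; models are compared with Mann–Whitney-U tests.

Shipped models: the four-species Goodwin-type **negative-feedback chain**
(`fb = 1/(1+(S4/kn1)^9)`) and the substrate-depletion
**positive-feedback chain** (`fb = 1 + (S4/kn1)^2`), each with optional
Michaelis–Menten kinetics per reaction and regulated-production variants,
plus a two-variable calcium oscillation model and a seven-variable
mammalian circadian model with their published reference parameter sets.

## Worked example

```r
library(oscrobust)

mod <- chainModel("negative")          # Goodwin-type chain, n = 9
ex <- runExperiment(mod, targetAccepted = 25, seed = 7)
ex
#> RobustnessExperiment: chain_neg_ma_conv_n9
#>   accepted 25 sets (sampled 134049, unstable 77, oscillating 44)
#>   sigma_T: median 0.194 (90% range 0.122)
#>   sigma_A: median 0.812 (90% range 3.58)
```

Of ~134,000 sampled steady states, 77 were linearly unstable, 44 oscillated
regularly, and 25 survived every parameter perturbation. The median period
sensitivity ~0.19 means a 1% parameter change typically shifts the period
by ~0.19%; its narrow 90% range shows that low period sensitivity is a
property of the negative-feedback structure itself, not of particular
parameter values. The amplitude is several-fold more sensitive and far
more variable across parameter sets — the published signature of this
design.

```r
summarizeDistribution(sensitivityRecords(ex)$sigmaT)
#> DistributionSummary (n = 25)
#>   median 0.1941 [notch 0.1899, 0.1982]
#>   IQR 0.01322 (q1 0.1838, q3 0.197)
#>   90% range 0.1216 (p5 0.1651, p95 0.2867)
```

The Hill-coefficient instability scan reproduces the onset of oscillations
at `n = 9` (negative feedback) and `n = 2` (positive feedback):

```r
sc <- instabilityScan("negative", nRange = 8:10, reduced = TRUE,
                      config = sampleConfig(seed = 1))
instabilityThreshold(sc)
#> [1] 9
```

A thin command-line front end over the same functions is installed at
`inst/cli/oscrobust.R` (subcommands `run`, `scan`, `compare`).

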