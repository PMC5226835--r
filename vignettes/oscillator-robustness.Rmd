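---
title: "Quantifying the robustness of period and amplitude in oscillator models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the robustness of period and amplitude in oscillator models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Cellular oscillators — circadian clocks, calcium spiking, p53 pulses —
differ sharply in how robust their period and amplitude are to parameter
perturbations. A circadian clock keeps near-24 h timing under widely varying
conditions; calcium oscillations change frequency readily, which is the
basis of frequency-encoded signalling. `oscrobust` implements a Monte-Carlo
framework for asking whether such robustness is a property of a model's
*structure* (feedback type, reaction kinetics, mass conservation) rather
than of any particular parameter values.

## The model class

A model is a declarative ODE system

$$\frac{dS_i}{dt} = \sum_{j=1}^{M} \eta_{ij}\,\nu_j , \qquad i = 1,\dots,m,$$

with strictly positive flows $\nu_j$ and more flows than species
($M > m$). Every flow is linear in exactly one *rate coefficient*
($\nu_j = k_j\,g_j(S,\theta)$, $k_j$ a rate constant or maximal velocity);
the kinetic factor $g_j$ may depend non-linearly on concentrations through
*nl-parameters* $\theta$ (Michaelis constants, inhibition/activation
constants) and through fixed *cooperativity parameters* (Hill exponents),
which are never sampled or perturbed. All models are dimensionless.

The shipped prototype oscillators are four-species chains with constant
production of $S_1$, chain conversions $S_1 \to S_2 \to S_3 \to S_4$
(reactions 2, 4, 6), and first-order degradations (reactions 3, 5, 7, 8).
The last species feeds back on reaction 2:

* negative feedback (Goodwin type): $fb(S_4) = \dfrac{1}{1 + (S_4/kn_1)^n}$,
  default $n = 9$;
* positive feedback (substrate depletion):
  $fb(S_4) = 1 + (S_4/kn_1)^n$, default $n = 2$.

The positive factor is *basal-plus-activation* rather than a saturating
Hill function: the basal term keeps the chain conversion running when
$S_4$ is low, which the substrate-depletion mechanism requires, and it
reproduces the documented instability behaviour — no unstable steady states
below the onset Hill coefficients (9 and 2), and an unstable fraction that
grows with the Hill coefficient and with $S_4/kn_1 \gtrsim 0.7$ for both
feedback signs. With a saturating activation factor instead, instability is
confined to $S_4/kn_1 < 1$ and the substrate-depletion statistics come out
an order of magnitude too sensitive, so that reading was rejected.

Each chain reaction 2–8 can individually use Michaelis–Menten instead of
mass-action kinetics (adding a Michaelis constant to the nl-parameters),
and each chain step 2, 4, 6 can be turned from a mass conversion into a
regulated production (the rate law keeps its dependence on the source
species, but the source's $-1$ stoichiometric entry is removed — the
information-transfer analogue of transcription/translation). Reaction 2 of
the positive-feedback chain must stay a conversion; without substrate
consumption there is no depletion mechanism and no sustained oscillation.

Two published oscillators ship as fixtures: the two-variable
phenomenological calcium model (cytosolic/store calcium with
calcium-induced calcium release; a substrate-depletion oscillator) and the
seven-variable mammalian circadian model (a transcription–translation
negative-feedback loop). Both carry their published reference parameter
sets; both were transcribed from the original publications and verified by
simulation (the calcium model oscillates with a period of a few time units
at its reference set, the circadian model with a period of about 23.8 h).
Further models can be supplied as structured YAML files
(`readModelYAML()`), including species tagged as probabilities (sampled on
$(10^{-3}, 1)$) and conserved moieties.

## Bottom-up sampling

Instead of sampling rate coefficients directly, the sampler draws a
complete steady state:

1. steady-state concentrations $S^0$, log10-uniform on $(10^{-3}, 10^3)$;
2. a balanced flow vector: $M - \mathrm{rank}(\eta)$ flows are selected in
   random order (a flow is kept as a free draw only while the remaining
   columns of $\eta$ still determine the dependent flows uniquely), drawn
   log10-uniform, and the rest solved from $\eta\,\nu^0 = 0$; the whole
   draw is repeated (cap: 1000 attempts) until the computed flows also lie
   inside the interval;
3. nl-parameters, log10-uniform on the same interval;
4. rate coefficients back-solved uniquely as $k_j = \nu^0_j / g_j(S^0,\theta)$.

Because concentrations and nl-parameters share one interval, saturation
terms cover all regulatory regimes — the median of a sampled
Michaelis–Menten term $S^0/(S^0 + K_M)$ is exactly one half. The
sensitivity statistics are invariant to shifting the sampling interval
(checked as a rank-sum test between runs on $(10^{-3},10^3)$ and
$(10^{-1},10^5)$), because only relative changes enter the sensitivities.

## Stability screening

The Jacobian at $S^0$ is assembled analytically from the factorised flow
derivatives; a steady state is unstable when some eigenvalue has positive
real part. Only unstable states — the candidates for limit-cycle
oscillations — are integrated. States with $|\max \mathrm{Re}\,\lambda| \le
10^{-12}$ are conservatively classified stable; for models with conserved
moieties the conservation-induced zero modes (the eigenvalues of smallest
modulus, one per moiety) are excluded first. The Hill-coefficient scan
(`instabilityScan()`) conditions sampled states on $S_4/kn_1$ ratio bins by
rejection and reports the unstable percentage per (Hill coefficient, bin);
the full published grid is $a = -6, -5.9, \dots$ with 10,000 states per
bin, and `reduced = TRUE` selects a coarse desk-scale grid
($a = -3, -2.5, \dots, 2.5$, 900 states per bin, i.e. more than 10,000
states per Hill coefficient) that still brackets the ratio region where
instability emerges.

## Dynamics: detection and confirmation

Integration starts at $0.95\,S^0$ (for conserved moieties, only the free
species are scaled and the dependent one restores the total). Two solvers
are implemented in compiled code: Dormand–Prince RK45 and a 4(3)-order
Kaps–Rentrop Rosenbrock method with analytic Jacobian (L-stable, one LU
factorisation per step). Both are probed with an equal computation budget
(10,000 accepted steps each) and the one that advances further in model
time continues — the work-based analogue of probing each solver for a
fixed wall-clock time. If the continuing non-stiff solver later shows
persistent rejection thrash (more than 12 derivative evaluations per
accepted step), the run escalates to the Rosenbrock method.

A solution is a *regular oscillation* when the species with the largest
observed max-minus-min shows five consecutive maxima equal within
$10^{-6}$ relative precision whose four inter-maximum intervals agree
within $10^{-4}$. Extrema are located from the sign change of the
derivative across an accepted step and refined on the cubic Hermite
dense-output interpolant. The interpolant has the same accuracy class as
the solver's continuous extension, so the equal-maxima rule implicitly
requires maxima smooth enough to be reproduced at $10^{-6}$ — razor-sharp
relaxation peaks fail it and are discarded as not-regular, which is the
conservative reading of the detection rule (sub-step re-integration of
each extremum would be more precise, but it admits a population of
extreme-relaxation parameter sets that visibly broadens the sensitivity
distributions beyond their published shape).

Detected oscillations are confirmed by re-integrating from the endpoint at
100-fold tightened tolerances (detection runs at rtol $10^{-6}$ / atol
$10^{-8}$, confirmation at $10^{-8}$/$10^{-10}$) over 100 periods; the set
is kept only when period and mean amplitude of the two passes agree within
$10^{-3}$ relative, and the confirmed (tightened-tolerance) values are the
ones reported. The period is the time between equal maxima; the amplitude
$A_i$ of each species is its max-minus-min over one period and the
reported amplitude is the arithmetic mean over species.

Budgets are deterministic step counts rather than wall-clock caps so that
results are machine-independent: integration is abandoned at 20,000 time
units or $3 \times 10^5$ accepted steps per detection run (confirmation:
$10^6$), corresponding to the same effective cut-off the original
wall-clock budget imposed, given the relative speeds of compiled and
interpreted right-hand sides. Runs exhausting the budget are discarded as
not-regular, exactly like runs exhausting the time horizon.

## Sensitivity analysis

For every accepted set, each of the $r$ perturbable parameters (all rate
coefficients and nl-parameters, never the Hill coefficients) is
individually multiplied by $1 + \delta$ (default $\delta = +2\%$) and the
full pipeline is re-run from the same $0.95\,S^0$ initial condition. The
coefficients

$$R^T_l = \frac{\Delta T / T}{\Delta par_l / par_l}, \qquad
  R^A_l = \frac{\Delta A / A}{\Delta par_l / par_l}$$

are aggregated into the overall sensitivities
$\sigma_T = \sqrt{\tfrac1r \sum_l (R^T_l)^2}$ and likewise $\sigma_A$. If
any perturbed system fails to yield a confirmed sustained oscillation, the
whole parameter set is discarded. Perturbed runs inherit the solver chosen
for the unperturbed system (a 2% parameter change does not alter the
stiffness class) and are confirmed over 10 periods instead of 100: the
unperturbed pass has already established the limit cycle, the perturbed
cycle is an $O(\delta)$ deformation of it, ten periods still contain the
required five equal maxima at the tightened tolerances, and period and
amplitude are extracted from the final period either way (checked: the
sensitivity distributions are statistically indistinguishable from runs
with the full 100-period perturbed confirmation). Alternative aggregations
(rate coefficients only; the three largest absolute coefficients) are
available via `altSensitivity()`.

Experiments (`runExperiment()`) loop sample → screen → simulate → perturb
until a target number of fully accepted sets. The full design uses 2,500
accepted sets per model; the bundled reproduction script uses 500 per
chain model, and the test suite uses 250 per chain model, 60/20 for the
calcium/circadian contrast and 80 for the interval-invariance comparison
— sizes chosen so the whole analysis reruns on a single CPU in well under
an hour while keeping the Monte-Carlo error of the medians at the level of
a few per cent. All randomness flows from a single seed through
R's RNG, including inside the compiled sampler, so runs are exactly
reproducible; every accepted record carries its draw index, and the
discard taxonomy (sampling failure, stable, not-regular, confirm-mismatch,
perturbed-*) is first-class in the accounting.

## Distribution summaries and comparisons

`summarizeDistribution()` reports median, quartiles, 5th/95th percentiles,
the 90% data range (the variability measure), and the notch interval
$\mathrm{median} \pm 1.57\,\mathrm{IQR}/\sqrt{n}$. Quantiles use linear
interpolation of the empirical CDF (R's default type-7 estimator; the
published analysis does not name its convention, and the acceptance
tolerances absorb the difference). Model comparisons use the two-sided
Mann–Whitney-U test (`wilcox.test`; exact for small tie-free samples). A
reported "p-value of zero" is represented as the smallest representable
p-value, never printed as exactly 0.

## What the generator emulates — and what it does not

The synthetic parameter sets emulate the *population of possible kinetic
states* of a fixed reaction topology: all steady-state concentrations,
flows and affinities within seven orders of magnitude, weighted
log-uniformly. They do not emulate measurement noise, stochastic kinetics,
correlated parameters, or biologically curated parameter ranges; passing
tests therefore validate the structural conclusions (which topology class
is robust) rather than predictions for any single organism's measured
rate constants.

## Known limitations

* Sensitivities are one-sided finite differences at $\delta = 2\%$; second
  derivatives of $\ln T$ with respect to $\ln par$ enter at $O(\delta)$.
* The desk-scale step budgets discard very slowly converging limit cycles
  that a larger budget would eventually accept; the effect on the medians
  is negligible but the extreme tails of the sensitivity distributions
  depend mildly on the budget.
* The stiff integrator is a fixed-order Rosenbrock 4(3); a variable-order
  BDF method would take roughly 2–3 times fewer steps at the confirmation
  tolerances.
* Bifurcation continuation, stochastic simulation and delay equations are
  out of scope.
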