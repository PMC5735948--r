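---
title: "Methods: a compartmental kinetics model of intestinal epithelial renewal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a compartmental kinetics model of intestinal epithelial renewal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptkinetics)
```

## The model and its assumptions

The package treats the renewing small-intestinal epithelium as ten
well-mixed compartments connected by first-order rate laws: crypt-based
columnar stem cells (CBC) feed transit-amplifying cells (TAC), which branch
into an absorptive limb (absorptive progenitors AP, then enterocytes EC)
and a secretory limb (secretory progenitors SP, then enteroendocrine EEC
and tuft TC cells directly, and goblet GC and Paneth PC cells through a
bipotent goblet/Paneth progenitor GPP). Differentiation rates are `k1..k9`,
proliferation rates `alpha, beta, gamma, delta, zeta`, and terminal loss
rates `lambda1..lambda5`; everything is per day, and counts are
real-valued averages per crypt-villus unit (CVU).

The assumptions this buys and their costs:

* **Linearity and mean-field mixing.** Every flux is proportional to a
  single compartment count. Spatial position along the crypt-villus axis,
  cell-cell signalling (Wnt/Notch gradients), cell-cycle age structure and
  stochastic birth-death fluctuations are deliberately outside the model.
* **Constant stem pool.** A stationary CBC count requires `k1 = alpha`
  exactly; this steady-state mode is the default everywhere. A non-steady
  mode (`k1 != alpha`, exponential stem pool) is supported by the ODE
  integrator for synthetic experiments only.
* **Empty start.** All compartments except CBC start at zero. This is the
  initial condition under which the closed forms below hold, and it is
  fixed rather than configurable.

Writing the net clearance of each proliferating compartment as a composite
rate (`omega_d = k2 + k3 - beta` for TAC, `omega_e = k5 - gamma`,
`omega_s = k4 + k6 + k7 - delta`, `omega_m = k8 + k9 - zeta`), the system
is a lower-triangular linear cascade with a constant source `k1 * CBC0`.
Finite steady states exist iff all four composite rates and all loss rates
are positive; `composite_rates()` flags violations rather than erroring,
because transient behaviour can still be of interest.

## Closed forms and their evaluation

Each downstream population is the terminal member of a chain of first-order
compartments driven by a constant source, so its time course is a
partial-fraction sum of exponentials:

$$X_n(t) = S \prod_k T_k \left[\frac{1}{\prod_i \mu_i}
  - \sum_i \frac{e^{-\mu_i t}}{\mu_i \prod_{j \ne i} (\mu_j - \mu_i)}\right]$$

where `S = k1 * CBC0`, the `T_k` are the transfer rates along the chain and
the `mu_i` its decay rates (for goblet cells, for instance,
`T = k3 k4 k8` and `mu = (omega_d, omega_s, omega_m, lambda4)`). This is
the integrating-factor solution of the cascade written generically; it
reduces to the familiar two- and three-compartment expressions (e.g.
`TAC(t) = (k1/omega_d) CBC0 (1 - e^{-omega_d t})`).

**Confluent rates.** The partial-fraction denominators vanish when two
decay rates coincide. Rather than implementing every confluent limit, the
package perturbs near-coincident rates (relative gap below 1e-9) by a
relative 1e-7 and warns; rates below 1e-12 are floored likewise. The error
introduced is of the order of the perturbation and is bounded in the test
suite by agreement with the numerical integrator. `t = 0` is special-cased
to exactly zero, where the analytic value is identically zero but floating
cancellation would leave ~1e-12 residue.

**Numerical oracle.** `integrate_ode()` solves the same system with
`deSolve` (lsoda, default relative tolerance 1e-9, absolute 1e-12). The
tests require closed-form/integrator agreement within a mixed tolerance of
1e-6 relative across random valid rate sets; the random generator enforces
a 5% mutual separation of decay rates so that it exercises the generic
branch, while the confluent branch has its own dedicated test.

**Renewal time.** The first time a population (or the ten-compartment
total) reaches a fraction of its steady state is found by bisection on the
closed forms to 1e-3 day within a 10,000-day horizon (both configurable).
Bisection is sufficient because every trajectory of a feasible rate set is
non-decreasing; a dense-grid scan cross-checks the root in the tests.

## Calibration per crypt-villus unit

A crypt-villus unit is one villus plus its average share of surrounding
crypts. With crypts and villi in a roughly hexagonal packing in the distal
small bowel, each villus receives, on average, **two** full crypt
contributions; per-crypt literature counts are therefore doubled, and
fractional abundances are scaled by the unit total `N = 4000` cells
(500 crypt + 3500 villus). The stem pool (10), transit-amplifying pool
(310), enteroendocrine (40), tuft (16), goblet (340) and Paneth (80)
counts are data; uncertainties scale with the same factors.

The three progenitor pools are not directly measured. The package assumes
each progenitor is proportional to the total steady-state population of
its progeny, with one shared constant `phi` anchored to the observed
goblet/Paneth-progenitor abundance (about 1% of the unit):
`phi = f_GPP * N / (GC + PC)`. From `phi` follow
`GPP = phi (GC + PC)`, `SP = phi [EEC + TC + (1 + phi)(GC + PC)]`, and,
by cell-count closure of the unit,
`EC = [N - (CBC0 + TAC + SP + GPP + EEC + TC + GC + PC)]/(1 + phi)` with
`AP = phi * EC`. After closure the ten targets sum to `N` exactly — the
conservation invariant the tests and the pipeline report both check.

Two source inconsistencies are worth recording. The source analysis quotes
a fast-scenario enterocyte target of 2848 cells while the closure above
gives 2844 with the same inputs; the package reproduces the closure and
uses the calibrated value for both scenarios (the fast scenario is
underdetermined regardless, so the 4-cell difference is immaterial). The
published fast-scenario value of the tied rate `k3` (0.125) is likewise not
exactly reproduced by its own defining relation evaluated at the published
free rates (~0.136); the package treats published fast values as one valid
solution, not ground truth.

Target uncertainties: the progenitor sigmas are propagated from the goblet
and Paneth sigmas through `phi`, the enterocyte sigma is the quadrature sum
of the component count sigmas through the closure, and the enteroendocrine
and tuft fractions — whose sources state no uncertainty — default to zero
with a config override.

## Tied rates

At each branch point the higher-subscripted rate is expressed through the
lower one and the steady-state ratio of the branch products:
`k7 = k6 (lambda3/lambda2)(TC/EEC)`,
`k3 = k2 (omega_s/omega_e)(SP/AP)`,
`k9 = k8 (lambda5/lambda4)(PC/GC)`. Because `omega_s` contains `k7`, `k7`
must be evaluated first; the implementation fixes this order. A useful
algebraic collapse checked in the tests: if `lambda4` is itself eliminated
through the goblet steady state, `k9` reduces to `lambda5 * PC/GPP`
(= 2/21 for the default targets) independently of `k8`.

## Fitting

**Scenarios.** The *baseline* scenario holds the experimentally known
rates fixed (`k1 = alpha = 1`, `beta = gamma = delta = zeta = 1.75`,
`lambda5 = 1/21` per day), shares the secretory loss rates
(`lambda3 = lambda4 = lambda2`), ties `k3, k7, k9`, and fits the seven
remaining rates to the seven steady-state targets
`{TAC, AP, SP, GPP, EEC, GC, EC}` (tuft and Paneth are satisfied
identically through the tied rates). The *fast* scenario frees all fifteen
non-tied rates, keeps `alpha = k1`, and appends one residual forcing
enterocytes to 95% of steady state at 5 days. The renewal residual enters
unweighted (weight 1): its natural scale, 5% of the enterocyte pool, is
already commensurate with the cell-count residuals, and the source analysis
states no weighting.

**Residuals and feasibility.** Residuals are unweighted model-minus-target
steady states, with tied rates recomputed at every evaluation. Where a
proposed point has any composite or loss rate below a 1e-4/day feasibility
margin, all residuals are replaced by a large finite penalty
`1e4 * (1 + deficit)` whose growth with the total constraint violation
gives the optimizer a way back to the feasible region. The residual vector
is zero-padded up to the number of free parameters because the
Levenberg-Marquardt backend requires at least as many residuals as
parameters; padding does not change the objective.

**Start values.** Naive starts (all rates 1/day) strand the optimizer in
local minima of this strongly nonlinear surface. The package instead
inverts the steady-state ratio relations target by target — choose the
manifold coordinate `k2`, then read `omega_e` off the AP/TAC ratio,
`lambda1` off EC/AP, `lambda2` off a linear closure of the secretory limb,
and so on. For self-consistent targets this initializer is an exact
solution; for noisy targets it lands near the optimum. The fast scenario
exploits a scaling symmetry: steady states depend only on rate *ratios*,
so multiplying every rate by `c` leaves them unchanged while compressing
time by exactly `c`; the baseline-style start is rescaled by the ratio of
its own 95% enterocyte renewal time to the 5-day constraint, which
satisfies all residuals at once, and the optimizer then polishes.

**Identifiability.** The seven baseline constraints pin only six parameter
directions: the SP residual is proportional to the AP residual once `k3`
is tied, so the residual Jacobian at any solution has rank 6 and the
solutions form a one-dimensional manifold. The identifiable quantities are
the per-compartment level ratios `omega_d`, `k2/omega_e`, `k4/omega_m`,
`k6/lambda2`, `k8/lambda4`, `lambda1/k5` — note that the composite rates
`omega_e, omega_s, omega_m` themselves are *not* identifiable: the
manifold trades `k2` against `omega_e` (and onward down the cascade) at
fixed ratios. `identifiability()` reports the numerical SVD rank (relative
tolerance 1e-8) and null-space directions; `fit_scenario()` warns whenever
the rank falls short of the number of free parameters. A *reproduction
mode* (`pin = c(k2 = 1.714495)`) removes the flat direction so the
published parameter table is recovered and uniquely determined. The fast
scenario is underdetermined outright (15 parameters, 8 residuals); its
published values are one point on a high-dimensional solution set.

**Uncertainties.** Free-parameter sigmas use the curvature method: each
fitted value is varied by ±1e-6 (absolute, as in the source analysis; a
relative-step option exists because absolute steps misbehave for rates far
above 1/day), the SSR increase is fitted to a quadratic `a d^2`, and
`sigma = sqrt(1/(2a))`; non-positive curvature is flagged as `NA` rather
than raised. Tied-rate sigmas are quadrature sums of the relative errors
of every factor in their defining expressions, with composite-rate sigmas
as quadrature sums of their additive components; the stem and progenitor
proliferation rates carry the literature 0.25/day. For the synthetic
round-trip tests the package instead propagates the *declared* target
sigmas through the estimator by the delta method with a pseudo-inverse
(`Cov = P J' S J P`, `P = (J'J)^+`): one-at-a-time curvature sigmas assume
unit residual variance and, with a single residual degree of freedom, an
estimated noise scale would be far too unstable for calibrated coverage
statements.

## Sensitivity analysis

`sensitivity_matrix()` differentiates the nine downstream steady states
with respect to all nineteen rates by central differences (step
`1e-6 * max(|r|, 1)`), each rate perturbed alone — including the tied
rates, which the source analysis also treats as independent inputs with
their own sigmas. The tests cross-check the full matrix against symbolic
differentiation of independently re-derived steady-state expressions and
against step-halving. `variance_matrix()` forms `V = S^2 sigma^2`
literally; its entries carry cells², not dimensionless units — rankings
within a row are nevertheless scale-free, which is how the matrix is used.
Rankings break ties by the canonical rate order.

With the published baseline rates and sigmas, every population ranks the
transit-amplifying proliferation rate `beta` first and the secretory
branching rate `k3` second; with the published fast values, `k3` leads for
every population. Both statements are asserted in the tests; finer
orderings are reported but deliberately not asserted, as they depend on
sub-percent details of the sigmas.

## Synthetic data

`generate_targets()` and `generate_timecourse()` draw noisy observations
from a known rate set — by default the published baseline set, so synthetic
experiments live in a realistic regime. Multiplicative gaussian noise with
a declared coefficient of variation mirrors the value-plus-uncertainty
structure of the literature counts; poisson noise mimics raw count data.
Non-positive draws are redrawn up to 100 times and then raise, avoiding
silent truncation bias. Identical seeds reproduce identical draws, and the
generator records the truth alongside the data.

What passing round-trip tests do and do not show: they demonstrate that
the estimator recovers the identifiable combinations from data whose noise
matches the declared model, with calibrated uncertainty (noise-free
recovery to 1e-4; 3-sigma coverage under 2% noise). They do not
demonstrate robustness to the ways real histology data deviate from the
model — section-sampling bias, staining efficiency, correlated errors
between cell types, or any spatial effect — none of which the generator
simulates.

## Numerical choices and problem sizes

* ODE tolerances 1e-9 (relative) / 1e-12 (absolute); closed-form vs ODE
  agreement asserted at 1e-6 mixed tolerance.
* Renewal-time bisection to 1e-3 day over a 10,000-day horizon.
* Optimizer: `nls.lm`, max 1000 iterations, `ftol = ptol = 1e-12`,
  non-negativity bounds at 1e-8.
* Property tests use 10–25 random rate draws per invariant; the recovery
  study uses 100 seeded replicates at 2% noise; monotonicity is asserted
  on a 0.1-day grid over 0–200 days. These sizes give stable verdicts for
  a linear ODE system of this dimension while keeping the default test run
  fast.

## Known limitations

* The model is deterministic and non-spatial by design; it cannot address
  clone dynamics, niche geometry, or fluctuation statistics.
* The central scientific finding it supports is negative: with literature
  proliferation rates, the total population needs on the order of 100 days
  to reach 95% of steady state, far from the observed ~5-day renewal; the
  fast scenario meets the timescale only with rates well outside measured
  ranges. The package reproduces both facts but cannot arbitrate between
  the biological explanations (effective stem-pool size, signalling
  feedback, age structure).
* Individual fitted rates in both scenarios are solver-dependent
  coordinates on solution manifolds; only the identifiable combinations
  deserve biological interpretation.
* The confluent-rate safeguard trades a bounded (warned) accuracy loss for
  simplicity; exactly coincident rates are measure-zero in practice but
  analyses tuned to sit on them should use the ODE integrator instead.
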