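---
title: "Modeling clonal competition in hematopoiesis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clonal competition in hematopoiesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdyn)
```

## The biological question

Blood production rests on a small pool of hematopoietic stem cells (HSCs)
in the bone marrow. With age, somatic mutations split this pool into
genetically distinct clones — clonal hematopoiesis of indeterminate
potential (CHIP) — and the niche that supports the pool degrades. Both
processes matter clinically for autologous transplantation: the graft may
carry a mutant clone, and the recipient marrow may no longer support the
cells it receives. `chipdyn` implements a deterministic population model
of these interactions and the analyses built on it: repopulation after
myeloablation, parameter sweeps, extinction-threshold detection,
growth-factor intervention, and inference of competition intensity from
observed stem-cell decline.

## Model structure and assumptions

The state is six populations: HSCs $H_1$ (healthy), $H_2$ (mutant) and
their mature myeloid ($M_1, M_2$) and lymphoid ($L_1, L_2$) descendants.

$$
\frac{dH_i}{dt} = r_i H_i\!\left(1 - \frac{H_i + h_j H_j}{K_H}\right)
 - \gamma H_i\left[\phi\sigma_M + (1-\phi)\sigma_L\right] - \delta_H H_i,
\qquad j \ne i
$$
$$
\sigma_M = e^{-(M_1+M_2)/K_M}, \qquad \sigma_L = e^{-(L_1+L_2)/K_L}
$$
$$
\frac{dM_i}{dt} = \alpha_M \phi\, H_i(t-\tau) - \delta_M M_i, \qquad
\frac{dL_i}{dt} = \alpha_L (1-\phi)\, H_i(t-\tau) - \delta_L L_i
$$

Key assumptions, in the model's own terms:

* **Shared niche, Lotka–Volterra coupling.** Both clones draw on one
  cytokine-limited carrying capacity $K_H$; the coefficient $h_j$ scales
  how strongly clone $j$'s occupancy counts against clone $i$'s logistic
  term. $h_1 = h_2 = 1$ makes the clones ecologically identical (a healthy
  marrow); $h > 1$ models niche overlap more hostile than self-crowding.
* **Demand-driven differentiation.** HSC loss to differentiation is not
  constant but proportional to the demand
  $D = \gamma[\phi\sigma_M + (1-\phi)\sigma_L]$, which decays
  exponentially as the mature compartments fill. $D$ is bounded by
  $\gamma$, reflecting a finite maximum differentiation rate.
* **Discrete maturation delay.** Committed cells surface as mature cells
  only $\tau = 14$ days later, amplified $\alpha$-fold. A discrete delay
  (rather than a distributed/linear-chain one) is used deliberately: the
  flux is not conserved through differentiation — cells amplify — which
  violates the linear-chain premise.
* **Uniform niche degradation.** Aging damage enters as one increment
  $\Delta \ge 0$ added to all three baseline death rates
  ($\delta = \delta_0 + \Delta$); both clones share one $\delta_H$.
* **Deterministic, population-level.** No demographic stochasticity, no
  engraftment bottlenecks, at most two clones, no spatial structure.

The degenerate healthy case is built in: with $h_1 = h_2 = 1$, $\rho = 1$
and equal clone states the two HSC equations are identical and their sum
follows a single-clone logistic-with-demand equation (asserted exactly in
the test suite).

## Parameters

Defaults of `hsc_params()` describe healthy clones; all units are cells
and days.

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `r1` | 0.1 | day⁻¹ | maximum healthy-HSC per-capita growth rate |
| `rho` | 1 | — | relative mutant growth rate; `r2 = rho * r1` (derived, never set directly) |
| `h1`, `h2` | 1 | — | competition exerted by clone 1 on clone 2 and vice versa |
| `K_H` | 10,000 | cells | HSC carrying capacity |
| `gamma` | 0.1 | day⁻¹ | maximal demand-differentiation rate |
| `phi` | 0.6 | — | myeloid fraction of differentiation (3:2 myeloid:lymphoid) |
| `delta_H0` | 0.001 | day⁻¹ | baseline HSC death rate (1/100 of growth) |
| `delta_M0`, `delta_L0` | 0.25, 0.1 | day⁻¹ | mature-compartment turnover |
| `alpha_M`, `alpha_L` | 1000 | — | amplification from commitment to maturity |
| `tau` | 14 | days | maturation delay |
| `K_M`, `K_L` | 90,000, 10,000 | cells | mature carrying capacities (9:1 split of a 100,000-cell local pool) |

Two unit conventions are worth making explicit because they are easy to
misread. The growth rates are treated as per-capita rates (day⁻¹) — the
logistic form only makes dimensional sense that way — and likewise
`gamma`, which multiplies a population in a rate equation, carries day⁻¹.

## Numerical integration

The delay system is integrated by `dde_integrate()` (C++ core):

* **Fixed-step classical RK4** at 0.01 days by default, i.e. the method of
  steps with the delayed state $H_i(t-\tau)$ looked up from the stored
  solution. Fixed stepping was chosen over adaptive error control for
  bit-reproducibility and exact alignment of event times; the convergence
  suite makes the accuracy auditable (fourth-order on a scalar linear DDE
  with an exact polynomial method-of-steps oracle, and final states at
  steps 0.01 and 0.005 agreeing to 10⁻⁶).
* **Cubic Hermite dense output.** Delayed lookups between grid nodes
  interpolate values *and* stored derivatives of the bracketing nodes —
  locally fourth-order, matching the integrator, so interpolation does not
  degrade the scheme. The constant pre-simulation history (100 cells per
  compartment by default) serves all lookups with $t-\tau \le 0$. Steps
  larger than $\tau$ are rejected, which guarantees every delayed lookup
  falls in the already-computed past.
* **Event alignment.** A growth-factor treatment (Heaviside drop of
  $\Delta$ to 0 at `treatment_time`) must fall on a step boundary; within
  any step $\Delta$ is constant, so the one-step method never integrates
  across the discontinuity. With the defaults (treatment at day 15, step
  0.01) this holds automatically.
* **Nonnegativity.** Populations are clipped at zero after each step; the
  clip count is recorded and warned about. Mathematically the flow cannot
  cross zero (every term vanishes with its compartment, asserted as a
  property test); clipping only guards against sub-roundoff undershoot.
* **Degenerate inputs.** Zero seeding is absorbing for HSCs; all-zero
  daughter compartments give the maximal demand $D = \gamma$. Far above
  capacity the demand underflows to exactly 0 in double precision (e.g.
  $e^{-3960}$); this is the correct limit and is tested as such.

## Experiments and conventions

`simulate_repopulation()` encodes the transplantation protocol: every
compartment seeded with 100 cells (matching the constant history), 280
days of growth. *Homeostasis* is by convention the state at day 280; a
settling diagnostic flags runs whose last-10-day relative change exceeds
10⁻⁴ (slow configurations, e.g. small `rho`, are re-run longer in the
tests rather than silently accepted). *Extinction* means fewer than 10
total HSCs at homeostasis.

`competition_growth_sweep()` and `niche_damage_sweep()` repeat the
protocol over $(h, \rho)$ and $(\Delta, h)$ grids (defaults
$[0.25, 3] \times [0.25, 3]$ at $25 \times 25$, and
$\Delta \in [0, 0.2]$ — chosen to bracket the regimes of interest: $h$
below, at and above 1, and damage across the extinction threshold).
Because the figure convention for the clonal ratio is ambiguous, the sweep
reports per-clone populations and the ratio $H_2/H_1$ with a $10^{-6}$-cell
floor (exclusion gives 0 or `Inf` rather than noise ratios).
`find_extinction_threshold()` scans a $\Delta$ grid and refines the first
extinct bracket by bisection to $10^{-3}$ day⁻¹.

## Steady-state oracle

`zero_demand_hsc_fixed_point()` solves the HSC equations in closed form in
the regime where demand is negligible (mature compartments far above
capacity, a condition *measured*, not assumed: the oracle is only asserted
against simulation where $D < 10^{-3}\gamma$). A design decision worth
recording: the function reports the fixed point *the repopulation protocol
converges to*, not merely the algebraic interior solution —

* $h_1 h_2 < 1$: the interior coexistence point (stable) where feasible,
  else the boundary point of the clone the other cannot invade;
* $h_1 h_2 > 1$ with exactly symmetric clones: the interior point, which
  is unstable to asymmetric perturbation but attracts the equal-seeding
  protocol along the invariant diagonal — this is precisely the regime the
  competition inference operates in;
* $h_1 h_2 > 1$ otherwise: bistable exclusion; from equal seeds the
  faster-growing clone wins (ties broken by the stronger exerted
  coefficient).

For marginal exclusion ($h = 1$, $\rho \ne 1$) convergence to the boundary
is asymptotic and much slower than 280 days, so only the total (which the
winner's level already determines) is compared against simulation.

## Inference of competition intensity

`infer_competition()` inverts the model by bisection on symmetric
$h_1 = h_2 = h$, evaluating each candidate by a full repopulation
simulation, until the homeostatic total matches
`observed_fraction × reference` to a relative 10⁻³. The homeostatic total
is strictly decreasing in $h$ (the solver asserts this on the bracket and
aborts otherwise), the default bracket $[10^{-3}, 50]$ expands
geometrically if needed, and unreachable targets (damage too severe,
fraction above 1 relative to the reference) raise a bracketing error with
the achievable range.

One genuinely open convention is the *baseline*: the surviving fraction
can be taken relative to the simulated healthy homeostatic total
(≈ $K_H(1-\delta_{H0}/r_1)$, i.e. 9,900 cells with defaults) or to the
carrying capacity $K_H$ itself (whose 20% is the rounder 2,000-cell
level). Both are supported (`baseline = "simulated"` (default) or
`"capacity"`); with a 20% fraction they give $h \approx 9.0$ and
$h \approx 8.9$ respectively — within the 2% band around the
zero-demand closed form $h = 2K_H(1-\delta_H/r)/\text{target} - 1$ that
the test suite checks. `decline_contour()` repeats the inference along a
$\Delta$ grid, tracing every (damage, competition) combination consistent
with one observed decline; $h$ falls monotonically with assumed $\Delta$,
and damage levels beyond reach are reported infeasible rather than
dropped.

`fit_competition()` wraps the chain cohort → decline estimate → Welch test
→ inversion into a single classed fit with `print`/`summary`/`coef`/
`predict` methods.

## The synthetic cohort generator

No raw animal counts ship with the package; `generate_cohort()` emulates
the *statistical structure* of a two-group flow-cytometry comparison of
young versus aged mice: $n = 5$ and $n = 6$ positive counts, log-normal
within groups (multiplicative biological variability, positive support)
with specified arithmetic means and coefficients of variation, the old
mean reduced by the target fractional decline (80% by default). The
young-group mean (10,000 cells) is an arbitrary scale — only the fraction
feeds the downstream inference. The default CV of 0.15 makes an 80%
decline at these group sizes almost always significant by Welch's test
(the `LSK`-like regime); CV ≈ 0.5 reproduces the power limitation of
rarer, noisier gates (`LSK-SLAM`-like), where significance is frequently
lost at $n = 5, 6$. What the generator does **not** emulate: instrument
effects, gating error, between-animal covariance, or any real count scale
— passing tests show the pipeline's statistics behave correctly, not that
real LSK data follow a log-normal.

`welch_t_test()` delegates to `stats::t.test(var.equal = FALSE)`; the test
suite cross-checks it against a hand-coded Welch–Satterthwaite evaluation,
and a 10,000-cohort null simulation confirms 5% ± 1% type-I error.

## Problem sizes and runtime

The compiled integrator makes the full protocol cheap (a 280-day,
0.01-day-step run takes ~30 ms), so the acceptance analyses run at full
resolution. Property sweeps in the test suite use a 0.02-day step — the
step-halving test justifies that resolution — and small grids
(3 × 3 rather than 25 × 25) chosen to cover every qualitative regime;
Monte-Carlo checks use 300 cohorts for power profiles and 10,000 for the
type-I calibration. The full suite and the acceptance script each complete
in well under a minute.

## Known limitations

* Mean-field and deterministic: no clonal drift, no engraftment sampling;
  near-extinct populations are real-valued fractions of a cell.
* Exactly two clones with symmetric competition in all headline analyses
  (`h1 != h2` is supported by the data model but not exercised by them).
* The inference returns a point estimate; uncertainty is limited to the
  bisection tolerance and the round-trip recovery property (< 1% on $h$).
* Homeostasis-at-280-days is a convention; slowly converging corners of
  parameter space (small `rho` at weak competition) need longer horizons,
  which the settling flag exposes.
* The $\Delta$-jump treatment model is instantaneous and uniform; no
  pharmacokinetics, no partial restoration.
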