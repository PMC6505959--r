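# chipdyn — clonal competition dynamics of hematopoietic stem cells

Clonal hematopoiesis of indeterminate potential (CHIP) means that an aging
bone marrow is not one stem-cell population but a mixture of a healthy and
one or more mutant hematopoietic stem cell (HSC) clones competing for the
same niche. `chipdyn` is an R package for scientists studying how that
competition, growth-rate disparities between clones, and aging-related
niche degradation jointly shape post-transplant blood reconstitution — and
for inverting the question: given an observed decline in stem-cell counts,
how intense must inter-clonal competition be to explain it?

## The model

Two HSC clones *H₁* (healthy) and *H₂* (mutant) renew logistically with
Lotka–Volterra cross-competition, lose cells to demand-driven
differentiation, and die:

    dH₁/dt = r₁H₁(1 − (H₁ + h₂H₂)/K_H) − γH₁[φσ_M + (1−φ)σ_L] − δ_H H₁
    dH₂/dt = r₂H₂(1 − (H₂ + h₁H₁)/K_H) − γH₂[φσ_M + (1−φ)σ_L] − δ_H H₂

The demand signals fall exponentially as the mature compartments approach
their capacities,

    σ_M = exp(−(M₁+M₂)/K_M),   σ_L = exp(−(L₁+L₂)/K_L),

and committed cells appear as mature myeloid/lymphoid cells only after a
maturation delay τ, amplified by successive divisions:

    dM_i/dt = α_M φ H_i(t−τ) − δ_M M_i
    dL_i/dt = α_L (1−φ) H_i(t−τ) − δ_L L_i

Niche degradation adds an increment Δ to all three death rates
(δ = δ₀ + Δ); the mutant growth rate is parameterized relatively,
r₂ = ρ·r₁. The six-dimensional delay system is integrated with a
fixed-step RK4 scheme (0.01-day resolution, cubic Hermite dense output for
the delayed lookup) written in C++.

## Worked example

Simulate repopulation of a myeloablated, moderately damaged marrow
(Δ = 0.05/day), then infer competition intensity from a synthetic mouse
cohort:

```r
library(chipdyn)

p <- hsc_params()                         # healthy defaults
rec <- simulate_repopulation(p, niche = niche_schedule(0.05))
rec$summary
#> Homeostasis at t = 280 d:
#>   HSC total 4900 cells (H1 = 2450, H2 = 2450; H2/H1 = 1)
#>   Myeloid 9.799e+06, lymphoid 1.307e+07 cells; demand D = 3.1e-49 /d
#>   Extinct (< 10 HSCs): FALSE; settled: TRUE
```

The damaged niche halves the homeostatic HSC pool (healthy level ≈ 9,900
cells) while demand feedback still keeps the mature compartments filled.
Now the inverse problem — a synthetic young/old cohort with an 80% true
decline in stem-cell counts, fitted by bisection over full repopulation
simulations:

```r
coh <- generate_cohort(young_mean = 10000, fractional_decline = 0.8, seed = 42)
fit <- fit_competition(coh, delta = 0)
fit
#> Inferred inter-clonal competition intensity
#>   Cohort decline: 78.9% (Welch t = 16.6, df = 4.59, p = 2.84e-05)
#>   Surviving fraction 0.211 of healthy reference 9900 cells (simulated baseline)
#>   Assumed Delta = 0 day^-1
#>   h1 = h2 = 8.497  (achieved 2085 vs target 2086 cells, rel. residual 0.00053)
```

This particular draw estimates a 78.9% decline (Welch's unequal-variances
t-test confirms it), and explaining the surviving 21.1% with competition
alone (Δ = 0) requires a coefficient h ≈ 8.5 — roughly an eight-fold
increase over the healthy h = 1. An exact 80% decline maps to h ≈ 9.

Other entry points: `competition_growth_sweep()` and
`niche_damage_sweep()` (steady-state grids over h, ρ, Δ),
`find_extinction_threshold()`, `growth_factor_intervention()`,
`decline_contour()`, `zero_demand_hsc_fixed_point()` (closed-form
steady-state oracle), and `run_pipeline()` with a YAML configuration. See
the methods vignette (`vignettes/clonal-competition.Rmd`) for the science
and all numerical choices.

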