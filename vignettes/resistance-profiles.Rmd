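---
title: "Depth-resolved SC resistance profiles: model, estimation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved SC resistance profiles: model, estimation and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scresist)
```

## The compartment model and its assumptions

The stratum corneum (SC) is treated as a stack of `n` uniform compartments,
one per sampling step of the Raman water profile (2 µm by default). Fick's
first law across compartment `i` relates the steady water flux to the
concentration drop across it; because at steady state that flux equals TEWL
in every compartment, the compartment resistance is identified directly:

$$R_i \;=\; \frac{W_i - W_{i-1}}{\mathrm{TEWL}} \qquad [\text{a.u.}]$$

`W_0` is the surface water concentration, `W_n` the concentration at the top
of the viable epidermis (the deepest retained sample). The unit is arbitrary
because mass% is a relative unit. Physically `R_i` conflates diffusion and
partition (`Δx_i / (D_i K_i)`); the two factors are not separately
identifiable from TEWL plus a water profile, so the package never attempts
to split them.

Key assumptions: the water profile is at steady state when measured; water
transport is one-dimensional; the viable epidermis below the SC acts as an
infinite reservoir. A telescoping identity,
`TEWL · ΣR_i = W_n − W_0`, holds *exactly* for every fit and is the
package's primary self-check.

A locally decreasing water profile yields a negative `R_i`. These are
retained with a warning rather than clamped: clamping would silently break
the conservation identity. They only become a problem in the dynamic model,
which rejects them (or, on request, floors them at
`1e-6 · median(R)`).

## SC thickness

The SC thickness sets which samples belong to the SC and normalizes depth.
The thickness algorithm used with the original clinical datasets is only
cited, not specified, so two explicit stand-ins are provided and the method
used is recorded in the fit metadata:

* **two_segment** (default): least-squares line through the rising portion
  of the profile (contiguous surface samples below 80% of the
  surface-to-plateau rise), intersected with the plateau level (mean of the
  deepest 20% of samples). Exact on piecewise-linear profiles; on noiseless
  sigmoids it lands within one sampling step of where the profile meets its
  plateau, and under 1.5 mass% noise it stays within ±2 µm of its noiseless
  value in ≥ 90% of seeded replicates.
* **plateau_fraction**: first sampled depth reaching 95% of the plateau
  level. Cruder but nearly failure-proof; pipelines use it as a fallback
  when the two-segment fit finds no plateau.

Flat profiles (no surface-to-plateau gradient) are rejected as
"thickness undeterminable". If the thickness is not a multiple of the
sampling step, the deepest sampled boundary at or below it maps to
normalized depth 1 — extrapolating unmeasured water values was deliberately
avoided.

## The resistance profile and its indices

Each `R_i` is a property of a slab, so it is anchored at the slab midpoint
in normalized depth and interpolated. Outside the outermost midpoints the
curve extends as a constant, which makes `R(0)` the outermost and `R(1)`
the innermost compartment's resistance — the boundary values the rate
indices use. Linear interpolation is the default: it can create no new
extrema, hence no spurious threshold crossings. A shape-preserving cubic
(PCHIP) is offered for smoother curves; a Fritsch–Carlson spline that does
not zero its slope at interior extrema was rejected because it overshoots
peak anchors by up to ~2%, visibly distorting the 80%-threshold geometry.

The indices summarise barrier formation, maintenance and degradation:
`R_max` and its depth `X_max`; the maintenance region `[X−, X+]` where the
curve stays above `0.8·R_max`; and the rates
`proR = (0.8·R_max − R(1))/(1 − X+)`,
`degR = (0.8·R_max − R(0))/X−`. The 80% threshold is a convention (and is
configurable); crossings are solved analytically on linear segments, which
removes any grid dependence. `X−`/`X+` are defined through the min/max of
the super-threshold *set*, so multi-peaked profiles (seen after petrolatum
application) are handled without special cases. When the curve never drops
below threshold at an end (`X− = 0` or `X+ = 1`) the corresponding rate is
reported as flagged-`NA`, never ±∞, so cohort statistics can drop those
subjects explicitly.

Discretization matters: compartment averaging flattens a kinked peak, so
pipeline indices converge to the analytic values of a known curve only
first-order in compartment width (measured: ~15% deviation at 10
compartments, under 2% at 80). Comparisons between cohorts measured on the
same grid are unaffected, but absolute index values should be read as
resolution-dependent.

## Cohorts and statistics

Subjects differ in SC thickness; profiles become commensurable only on the
normalized grid, so group averaging happens *after* interpolation onto a
common grid (101 points by default). Indices are computed per subject and
then averaged — not computed on the mean profile — because that is the
estimand the cohort comparisons need; the indices of the mean profile are
also reported for inspection. Two groups are compared with a two-sided
pooled-variance Student's t-test (a Welch option exists behind a flag),
three or more with one-way ANOVA; with equal variances assumed the
two-group F equals t², which the tests verify. No multiple-testing
correction is applied across the six indices, and treatment (oil) effects
are reported descriptively — a relative-change curve
`100·(after − before)/before` per depth with max/mean summaries — without a
paired test.

## The dynamic model

Interior compartments evolve by
`dW_i/dt = (W_{i−1} − W_i)/R_i + (W_{i+1} − W_i)/R_{i+1}`, with `W_0(t)` a
piecewise-constant boundary schedule and `W_n` fixed. The equations carry an
implicit unit compartment capacity — time is in seconds only up to that
constant — and a single global `capacity` parameter (default 1) is exposed
for physical calibration. Integration uses the adaptive Runge–Kutta pair
`ode45` (rtol 1e-6, atol 1e-9 by default) and restarts exactly at schedule
discontinuities, so square pulses are not smoothed. The standard
absorption–desorption protocol raises `W_0` by 60 mass% during t = 10–20 s
of a 50 s horizon (a typical baseline `W_0` of 30 mass% reaches 90 mass%
under the applied water). Verification is oracle-based: the closed-form
steady state against a tridiagonal solve, trajectories against the
matrix-exponential solution of the linear system (max-abs error ~1e-6 at
default tolerances), plus fixed-point, superposition and
convergence-to-steady-state properties. Total SC water content sums the
interior compartments only; the boundaries are reservoirs. The conductance
scaling `k = Σs·m / Σs²` is the closed-form least-squares solution, checked
against a numeric minimiser.

## The synthetic-data generator

Ground truth is specified in resistance space — a piecewise-linear curve
over normalized depth (tent, two-peak, or constant) — and water profiles
are derived from it by inverting the compartment relation. This direction
makes recovery tests exact by construction at zero noise: the fitted `R_i`
equal the compartment-averaged truth to machine precision. Defaults emulate
healthy adult volar forearm skin and are held fixed as the package's study
conditions: SC thickness 20 µm at 2 µm sampling, surface water 30 mass%
rising to ~70 mass%, TEWL lognormal with mean 10 g·h⁻¹·m⁻² and CV 0.3
(lognormal because TEWL is positive and right-skewed), additive Gaussian
noise of 2 mass% on water values (Raman-typical), between-subject lognormal
scaling of the whole resistance curve with CV 0.15, and a logistic ~4 mass%
plateau transition appended beyond the SC so thickness estimators see
realistic shapes. Every draw is determined by a master seed plus the
subject id, and the caller's RNG state is left untouched.

What the generator does *not* emulate: depth-dependent or correlated
measurement noise, instrument drift, subject covariates (age, site) beyond
group-level parameter shifts, or deviations from steady state. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the stated noise model, not performance on any particular
clinical dataset.

One consequence of the model structure deserves emphasis: `R_i` is a first
difference of noisy water values divided by TEWL, so its noise is
`√2·σ_W/TEWL` ≈ 0.28 a.u. against a true peak of ~0.7 a.u. under the
defaults, and `R_max` is a maximum over ~10 such estimates, adding a
positive selection bias. The measured median relative error of per-subject
`R_max` at 2 mass% noise is ~33%. Per-subject peak resistance from raw 2 µm
first differences is intrinsically noisy; cohort-level averages and
comparisons remain well calibrated (type-I error 4.6% at the nominal 5%
over 1000 seeded replicates), which is how the indices are meant to be
used.

## Problem sizes and numerical choices

Test and verification runs use 10–80 compartments, cohorts of 6–12 subjects
(100 for recovery error, 1000 replicates for calibration), 50 s simulation
horizons at ~500 output points, and grids of 101–1001 points — sizes chosen
so the full suite exercises every code path in well under a minute of
compute per property. Ties in peak location break toward the surface;
super-threshold membership uses a 1e-12-relative tolerance so anchors lying
exactly on the threshold are included; round-tripped tables preserve at
least 12 significant digits.

## Known limitations

* Resistance cannot be split into diffusion and partition components from
  these data.
* The dynamic model is linear with concentration-independent resistances;
  evaporation physics, water–NMF binding kinetics and 2-D/3-D geometry are
  out of scope.
* Absolute index values depend on sampling resolution (first-order), and
  per-subject `R_max` carries substantial noise at clinical noise levels —
  see above.
* The thickness estimators are documented stand-ins, not the literature
  algorithm used with the original datasets; both are deterministic and
  labelled in output metadata.
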