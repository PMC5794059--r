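---
title: "Models and methods behind quorosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quorosc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(quorosc)
```

This vignette documents the models, the numerical choices and the open
design decisions of the package, in the spirit of a methods supplement.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The cell models

The plain oscillator is the Danino-type synchronized clock: an
AHL-activated promoter drives both the activator LuxI and the repressor
AiiA after a transcriptional delay `tau`, AiiA degrades AHL, and external
AHL diffuses between cells.  The model state per cell is
`(A, I, Hi, He)`; production of `A` and `I` carries the density prefactor
`1 - (d/d0)^4` and the delayed Hill drive
`P = delta + alpha*Htau^2/(1 + k1*Htau^2)`, degradation saturates
Michaelis–Menten style with shared coefficient `f`, and the external pool
decays at flow rate `mu`.  The published form of the external-AHL
equation prints a second *time* derivative on the diffusion term while
the accompanying text describes Fick's second law; the package implements
the term as a spatial Laplacian along the cell array, which is the only
reading under which the term couples neighbouring cells.

The light-gated variant adds a repressor `R` and a two-component light
sensor `TC`.  Both AiiA and `TC` production are multiplied by the
repression factor `K^n1/(R^n1 + K^n1)`; `R` is produced through the
sensor Hill term `alpha_TC*TC^n_TC/(TC^n_TC + K_TC^n_TC)` only while the
ambient light matches the channel's activating condition.  The model
equations use the AiiA degradation machinery for `TC`; `gamma_TC` is
exposed as an optional override but defaults to `gamma_A` as printed.
With the gate closed and `R = TC = 0` the variant's `(A, I, Hi, He)`
derivatives coincide *formula for formula* with the plain model — the
test suite asserts bitwise agreement at random states.

## Parameter provenance

The baseline rate constants are the package's transcription of the
published synchronized-clock model (`C_A = 1`, `C_I = 4`,
`delta = 1e-3`, `alpha = 2500`, `k1 = 0.1`, `tau = 10` min,
`gamma_A = 15`, `gamma_I = 24`, `gamma_H = 0.01`, `f = 0.3`, `g = 0.01`,
`k = 1`, `b = 0.06`, `d0 = 0.88`, `D = 2.5`).  Two quantities are not
fixed by that source and were chosen once, before any experiment was
frozen, so that the bulk model oscillates with an hour-scale period under
the study overrides: cell density `d = 0.5` and external flow
`mu = 0.1`/min.  The synchronization experiments use the study overrides
`gamma_A = 23`, `gamma_H = 0.023` and extracellular diffusion
`D1 = 100` um^2/s (`study_params()`).

The repressor-channel Hill parameters are likewise not printed in the
source beyond `K = 100` and `gamma_R = 1.5` for the TetR-class repressor.
The package's defaults — `alpha_TC = 40`, `K_TC = 800`, `n_TC = 2`,
`n1 = 2` — were selected by a pre-registration screen against the
*qualitative* structure the circuit is reported to have: a genuine Hopf
bifurcation in `gamma_R` with a supercritical window in which period and
amplitude both rise with `gamma_R` toward the unrepressed limit, exact
reduction to the plain model for weak repression, and an active
repression factor at the study point.  A mechanistic note: a sensor with
a high half-activation (`K_TC = 800`, above typical `TC` excursions)
keeps repressor production graded, so `R` averages over the fast cycle
and the repressed orbit stays regular; saturating sensors put the
repressor's relaxation time on the cycle timescale and produce
mixed-mode oscillations.  The UV channel shares the Hill shape with
`gamma_R = 0.01`, below the Hopf boundary (~0.032 at `K = 100`), which
implements the oscillation kill switch.

## The integrator

Delay systems with one constant delay are integrated by the method of
steps: fixed-step classical RK4 with the delayed state obtained by cubic
Hermite interpolation of the stored solution.  Design points:

* The solution's derivative generally jumps at `t = 0` (history vs
  model); delayed lookups before zero therefore interpolate the sampled
  history only and never straddle the origin.  This keeps the
  piecewise-polynomial test problem `y' = -y(t-1)` exact to machine
  precision at `t = 1` and `t = 2`.
* The default step is `min(tau/20, 0.05)` min.  Colony runs additionally
  obey the explicit-diffusion stability bound
  `D1c * step / dx^2 <= 0.45` (with `D1c` in um^2/min);
  a configuration violating `0.5` is rejected rather than silently
  subdivided.  At the study values (`D1 = 100` um^2/s, `dx = 10` um) the
  bound gives a step of 7.5 ms of model time, i.e. ~67k steps per
  500-minute colony run — the reason the stepping core is compiled.
* Memory stays bounded via a ring buffer holding one delay-window of
  fine-grid states; the returned trajectory is thinned (default ~0.25
  min resolution) with derivatives retained, so dense evaluation remains
  fourth-order accurate on the output grid.
* Concentrations are clamped to zero after each accepted step; an
  undershoot beyond `1e-8` times the running species maximum raises a
  warning rather than being silently absorbed.
* Cell spacing defaults to 10 um.  The robustness conclusions were
  checked to be insensitive to doubling it (the bound then allows a 4x
  larger step).

No adaptive stepping is attempted; determinism (bitwise-identical
trajectories for identical inputs, including seeds) is a design goal and
is tested.

## Classification and cycle measurement

A post-transient window (default: the last 60% of the horizon for
sweeps, the last 50% for robustness classification) is labelled
*oscillatory* when its range exceeds `rel_tol * max(1, mean)`
(`rel_tol = 1e-3`) and it contains at least three local maxima whose
inter-peak intervals have a coefficient of variation below 0.2.  Peaks
are plateau-aware local maxima with a prominence floor.  The period is
the mean inter-peak interval; the amplitude is half the peak-to-trough
range over the last three cycles, a definition robust to slow drifts.
Irregular (e.g. mixed-mode) signals deliberately fall back to
*steady_state* rather than reporting a meaningless period.

The Hopf boundary is localised by bisection between a steady and an
oscillatory bracket endpoint, replacing continuation software.  The
approach is validated against the scalar linear delay equation
`y' = -a y(t - tau)`, whose boundary is analytically `a*tau = pi/2`
(from the characteristic equation `lambda = -a e^{-lambda tau}`); the
simulation-based boundary lands within 5%.

Sweeps near the supercritical onset use long horizons (3000 min for the
`gamma_R` tunability sweep) because cycle properties settle slowly just
above a Hopf bifurcation; with shorter horizons the measured period
still carries transient drift.

## Synchronization metrics

ASE at one time is the mean absolute nearest-neighbour AiiA difference
around the periodic ring.  The accompanying text of the source mentions
normalizing by the oscillation amplitude while its printed formula has no
such factor; the package implements the printed formula and offers
normalization behind a flag (off by default).  IASE is the trapezoidal
integral of ASE over the horizon (500 min in the study configuration).
The synchronization rate `r` comes from least squares on the log of the
ASE maxima over the whole horizon — an envelope fit; maxima below 1% of
the ASE range are excluded so that the fit tracks the envelope rather
than numerical floors.  Perfect synchrony (ASE identically zero) is
reported as an `r = Inf` sentinel with a flag, not an error.

## The robustness study

At each grid point of a two-parameter degradation space, both circuits
are classified in bulk (single cell, diffusion dropped, no noise); where
both oscillate, 6-cell colonies of each circuit are integrated for 500
minutes from the *same* noisy initial state (LuxI = 100 + U(0, 400)
a.u., everything else zero; paired design, shared seed).  The gated
circuit is counted more robust where `IASE_danino - IASE_hotfm > 0`
(less integrated desynchronization) and where
`r_danino - r_hotfm < 0` (slower plain-circuit synchronization).  Exact
ties are excluded and reported.

The default study pools two spaces chosen to straddle both circuits'
Hopf branches: `gamma_I` in [8, 40] x `gamma_A` in [5, 40] (7 x 8
points) and `gamma_H` in [0.005, 0.1] x `gamma_A` in [5, 40] (11 x 10
points), giving over 100 common-region points, with the second space
weighted more heavily — mirroring the relative sizes of the two reported
point sets (520 vs 1510).  The exact grids behind those published counts
are not printed; the package's grids are its own defaults, exposed as
configuration, and the robust-fraction *values* are therefore
grid-dependent even though the majority conclusion is not expected to
be.

Aggregate uncertainty uses the percentile bootstrap (B = 1000 resampled
means of the robust-indicator vector); the effect size is Cohen's *d*
between that bootstrap distribution and the means of equally many
Bernoulli(1/2) vectors, with equal-weight pooled SD
`sqrt((s1^2 + s2^2)/2)` — with equal B on both sides the pooling weights
are immaterial.  A closed-form check: the bootstrap SD of a fraction p
over n points is `sqrt(p(1-p)/n)` and the reference SD is
`sqrt(0.25/n)`, so d ~ `(p - 0.5)/sqrt((p(1-p) + 0.25)/(2n))`, which
reproduces the reported effect sizes from their printed counts.
Per-point effects bootstrap the n = 6 per-pair metric values of each
model independently (joint paired resampling available behind a flag)
and report the 95% percentile interval of the difference and whether it
contains zero.

## Beats

Two blocks of cells running at nearby frequencies superpose at their
interface; the mean of the two flanking cells' signals shows amplitude
modulation at `|f1 - f2|` (sum-to-product identity, used as the test
oracle).  The aggregation rule at the interface is not specified by the
source; the package uses the arithmetic mean with a sum option.  The
beats experiment runs with *noise-free* initial conditions: beats are a
deterministic interference phenomenon, and a noise-free homogeneous
control stays strictly periodic (modulation depth ~1e-4), making the
mixed colony's modulation unambiguous.  With noisy starts a large
homogeneous colony remains internally desynchronized for hundreds of
minutes and its own peak-height variability would confound the
comparison.  Modulation is quantified as the coefficient of variation of
carrier-peak heights after a 300-min transient.

## What the synthetic conditions do and do not show

The generator emulates the study conditions: identical cells, static
density, one-dimensional periodic geometry, initial-condition noise on
LuxI only, deterministic dynamics otherwise.  It does not emulate cell
growth and division, stochastic gene expression, spatial
two-dimensional colonies, or microfluidic flow heterogeneity — passing
tests therefore validate the model implementation and the statistical
pipeline, not the biology of a real colony.

## Known limitations

* The repressed circuit develops mixed-mode (irregular) oscillations in
  parts of the `(alpha_TC, K_TC, gamma_R)` space; the classifier labels
  these *steady_state* by design, which makes boundary estimates in such
  regions conservative.
* The kill switch leaves a small AiiA remnant (a few percent of the
  oscillation peak) because repression is Hill-type, not absolute; LuxI
  settles at an elevated plateau rather than growing without bound once
  its saturating degradation balances production.
* `r` estimates on nearly synchronized colonies are sensitive to the
  prominence floor; comparisons between models are therefore made under
  a shared estimator configuration.
* The fixed-step integrator trades speed inside the diffusion stability
  bound for the absence of error control; the step-halving convergence
  test and the deSolve cross-check bound the discretisation error on the
  study horizon.
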