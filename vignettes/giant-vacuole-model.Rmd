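---
title: "Modelling giant-vacuole formation by inverse blebbing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling giant-vacuole formation by inverse blebbing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvbleb)
```

## The physical picture

A Schlemm's-canal endothelial cell sits on a porous basement membrane with a
basal-to-apical pressure drop $\Delta p$ across it. Where the actomyosin
cortex is locally disrupted over a pore of half-width $a$, the pressure
inflates the basal membrane *into* the cell: an inverse bleb, which can
mature into a giant vacuole (GV). `gvbleb` integrates a minimal mechanical
model of one or more such invaginations in a single cell.

The bleb is a spherical cap of radius $r$ and opening angle $\theta$
constrained by the pore, $r\sin\theta = a$ with
$\pi/2 \le \theta \le \pi$; the cell remains a hemisphere of radius $R$.
Three assumptions close the model:

1. **Overdamped interface dynamics.** The radius follows a Rayleigh–Plesset
   balance without inertia,
   $\dot r = \frac{r}{4\mu}\left[\Delta p - P - \frac{2\Sigma}{r}\right]$,
   where $\mu$ lumps all resistance of the cell interior into one effective
   viscosity.
2. **Fast pressure equilibration.** The intracellular gauge pressure is
   always at its Laplace value $P = 2\sigma/R$.
3. **No leakage.** Cell volume is conserved exactly:
   $R^3 = R_0^3 + \sum_i 2 r_i^3 (2+\cos\theta_i)\sin^4(\theta_i/2)$.

All pressures are gauge pressures relative to the canal: only pressure
*differences* enter the dynamics, so the external pressure is set to zero
and the applied drop $\Delta p$ is the only pressure input. Internally the
package works in $\mu$m / s / pN (pressures in pN/$\mu$m$^2$, numerically
pascals); mmHg is accepted only at the interface
(`mmHg_to_pN_um2()`, `delta_p_mmHg` arguments and config keys).

## The two-regime tension law

Surface tension is slaved to relative area strain. For the bleb the relevant
area is the membrane patch of radius $d$ over which its tension can
equilibrate within a GV lifetime:
$S = \sum_i 2\pi r_i^2(1-\cos\theta_i) + \pi(d^2 - n a^2)$ for the $n$ blebs
on the patch, with resting value $S_0 = \pi d^2$ and strain
$\varepsilon_B = (S - S_0)/S_0$. For the cell,
$A = 3\pi R^2 - k\pi d^2$ with $k$ patches excised and
$\varepsilon_C = (A - A_0)/A_0$.

* **Cortex-dominated regime** ($\varepsilon \le \varepsilon^*$): membrane
  reservoirs (caveolae, wrinkles, microvilli, exocytosis) buffer all area
  increase, so the target tension is the constant plateau
  $\sigma_0 = \sigma_m + \sigma_c$. The bleb's contractile shell, disrupted
  at nucleation ($\Sigma(0) = \sigma_m$), relaxes toward it exponentially on
  the actin-turnover time: $\dot\Sigma = (\sigma_0 - \Sigma)/\tau_c$.
* **Membrane-dominated regime** ($\varepsilon > \varepsilon^*$): reservoirs
  are spent and further area comes from elastic stretch. Tension
  equilibration in the taut, fluid membrane is much faster than every other
  process, so it is taken as instantaneous:
  $\Sigma = \bar\Sigma = \sigma_0 + K_m\left[e^{(S-S^*)/S^*} - 1\right]$
  with $S^* = S_0(1+\varepsilon^*)$.

The law is continuous at the threshold ($\bar\Sigma(S^*) = \sigma_0$), which
is why the regime switch needs no special event handling in the integrator
(see *Numerical choices*). The same functional form governs the cell
tension; in practice a single vacuole never strains the cell past
$\varepsilon^*$ for pressures up to at least 30 mmHg, so
$\sigma = \sigma_0$ throughout (asserted in the test suite rather than
hard-coded).

## Parameters

| field | meaning | default | units |
|---|---|---|---|
| `R0` | resting cell radius | 10 | $\mu$m |
| `a` | basal pore half-width | 0.25 | $\mu$m |
| `sigma_m` | membrane entropic tension | 40 | pN/$\mu$m |
| `sigma_c` | cortical tension | 374 | pN/$\mu$m |
| `K_m` | area-expansion modulus | $10^5$ | pN/$\mu$m |
| `d` | tension-equilibration patch radius | 10 | $\mu$m |
| `eps_star` | reservoir threshold strain | 0.5 | — |
| `tau_c` | cortex turnover time | 1 | s |
| `mu` | effective viscosity | $2.5\times 10^4$ | pN s/$\mu$m$^2$ |

`sigma_0` is always the derived sum (414 pN/$\mu$m at reference). The
defaults are the reference point used throughout the package's tests;
plausible physiological ranges are roughly 9–11 $\mu$m for `R0`, 5–12
$\mu$m for `d`, and reservoir strains from a few percent up to 100%
(`eps_star` admits up to 3 for exploration of super-stretched states, whose
strain-softening physics is deliberately *not* modelled). `validate_params()`
enforces positivity, $a < d \le R_0\sqrt 3$, $a < R_0$ and the exact
derived-sum constraint.

## Steady states, thresholds, stability

Setting $\dot r = 0$ with tensions at their targets gives the balance
$\Delta p = 2\bar\Sigma(r)/r + 2\bar\sigma(r)/R(r)$. Its left side is
strictly decreasing in $r$ while the reservoir lasts (the cortex branch,
$\bar\Sigma = \sigma_0$) and strictly increasing once the exponential takes
over (the membrane branch), so each branch holds at most one root and
`gv_equilibria()` brackets them separately — no dense scanning, no missed
roots. The branches meet at the reservoir-exhaustion radius $r^*$ (where
$S(r^*) = S^*$), which is therefore the saddle-node:

* $\Delta p^* = 2\sigma_0(R + r^*)/(R r^*)$ — the nucleation threshold,
  below which no equilibrium exists (`nucleation_pressure()`; ~2.36 mmHg at
  reference). It scales linearly with $\sigma_0$ and falls as
  $\varepsilon^*$ grows.
* $\Delta p^\dagger$ — where the cortex root reaches the pore radius
  $r = a$ and leaves the admissible domain (`bistability_pressure()`,
  evaluated as the balance at $r = a$, essentially
  $2\sigma_0/a + 2\sigma_0/R_0$; ~25.5 mmHg at reference). The model names
  this threshold but gives it no closed definition elsewhere; "cortex root
  exits at $r = a$" is this package's operationalisation.

Stability is classified on the tension-slaved one-dimensional reduced
dynamics (the fast-tension limit): sign of $d\dot r/dr$ at the root by
central difference with step $10^{-6} r$. Membrane-branch equilibria come
out stable, cortex-branch ones unstable — the cortex root is the threshold
nucleation radius (~0.97 $\mu$m at 7 mmHg: nuclei below it deflate, above
it grow). `pressure_scan()` tabulates the resulting 0/2/1 branch pattern
across pressure and refines $\Delta p^*$ independently by bisection on root
existence (to $10^{-3}$ mmHg); the agreement of the bisected threshold with
the closed-form estimate is one of the package's cross-checks.

## Numerical choices

* **Integrator.** `deSolve::lsodar` (adaptive, switches to BDF when stiff)
  at `rtol = 1e-8`, `atol = 1e-10`. The membrane-regime exponential makes
  the approach to the steady GV stiff; the rest of the trajectory is not.
* **Events.** Collapse ($r = a$) and the lytic overflow guard are *terminal
  integration roots*, located by the solver's root finder rather than by
  stepwise checks, so first-passage times are resolved to integrator
  precision. Regime switches are *not* roots: the tension law is continuous
  at $\varepsilon^*$, so the RHS has only a kink there; switch times are
  annotated post hoc from the dense output.
* **Algebraic slaving.** $\theta$, $R$, $A$, $\sigma$, $P$ and the
  membrane-regime $\Sigma$ are recomputed from $r$ (and the patch state) at
  every RHS evaluation; only $r_i$ and the relaxing $\Sigma_i$ are ODE
  states, so volume conservation and the Laplace law hold to machine
  precision by construction (asserted at $10^{-9}$ relative in the tests).
* **Degenerate threshold crossing.** If the membrane regime were entered
  before cortical relaxation completed (possible only for pathological
  $\tau_c$ far above the growth time), the effective tension is
  $\max(\Sigma_{\text{relax}}, \bar\Sigma)$, preserving continuity and
  monotone loading. At reference parameters relaxation completes in seconds
  while exhaustion takes minutes, so this guard never activates.
* **Overflow guard.** The strain exponent $(S-S^*)/S^*$ is capped at 50;
  crossing the cap ends the run with a `lytic` event (the exported
  `target_tension()` errors instead). Membrane rupture at high strain is
  real but its location is uncertain, so the bound is configurable and
  nothing quantitative is asserted about it.
* **Collapse bookkeeping.** A bleb reaching $r = a$ is frozen there, its cap
  removed from the patch area and the volume budget while its pore stays
  excised; survivors continue. The model is only declared valid down to
  $r = a$, and what happens to a shared patch after a partner collapses is
  not specified by the physics — this convention is the package's choice.
* **Criteria for reported times.** "Time to steady state" is first entry
  into $\pm 1\%$ of the steady radius; "collapse time" is first passage to
  $r = a$. The underlying observations are only "about N minutes", so the
  package fixes sharp, reproducible criteria and documents them.

## Multiple vacuoles and coarsening

Vacuoles nucleated farther apart than $d$ sit on independent patches: apart
from the (weak, $\sim 10^{-4}$ relative) coupling through the shared cell
volume they behave exactly like single GVs. Vacuoles nucleated closer share
one patch: one area budget $S$, hence one target tension for all of them.
While the shared reservoir lasts they grow independently; once it is
exhausted the configuration with equal radii becomes unstable — of two blebs
at the symmetric zero of the slaved velocity field, the larger grows and the
smaller shrinks (`ripening_field()` exposes this phase portrait). The
outcome is Ostwald-like coarsening: a fraction-of-a-percent initial
imbalance at 7 mmHg amplifies over ~10 min until the loser collapses and
the winner matures to (within 1% of) the single-GV steady radius
(`gv_simulate_multi()`, `coarsening_summary()`). Sharing also shrinks the
per-vacuole reservoir, raising $\Delta p^*$ and reducing the maximal size
(`shared_patch_shift()`). Sterics, contact deformations and bleb positions
are not modelled; "closer/farther than $d$" enters only as the
shared/independent flag.

## Parameter-variability ensembles

`ensemble_spec()` + `draw_params()` perturb chosen parameters independently
and multiplicatively, uniform on $[1-f, 1+f]$ with $f = 0.2$ by default —
"up to 20% variability" read in the minimal way; no correlations are
imposed because none are known. Draws are rejected (and redrawn) if they
violate the parameter invariants, and are bitwise reproducible given the
seed. `dynamics_ensemble()` classifies each draw's trajectory
(shrink / grow-to-steady / not-converged); `steady_ensemble()` records each
draw's thresholds and its equilibrium-count pattern at probe pressures
below, between and above them. At the reference point the qualitative
results — growth to the membrane-branch GV at 30 mmHg, the 0/2/1 branch
pattern — survive all draws (100 dynamical, 500 steady in the acceptance
suite).

## What the model does and does not capture

The simulated conditions are the idealised perfusion experiment: a clean
pressure step, one or two vacuoles, a hemispherical cell, constant pore and
patch sizes. Passing tests therefore demonstrate internal consistency and
the model's qualitative predictions under these conditions — not fidelity
to the full biology. Known omissions, each deliberate: membrane bending
rigidity (negligible at these radii); confined-geometry corrections to the
interface equation (small for $r/R \lesssim 0.2$); tension diffusion and a
time-dependent patch radius $d(t)$; super-elastic strain softening beyond
~100% strain; nucleation kinetics (nucleation enters only as the initial
condition $r_0 = a$, $\Sigma_0 = \sigma_m$); and any elastic (non-viscous)
response of the cell interior. Real GVs are ellipsoidal, not spherical
caps, and real cells carry broad pore-size distributions — the ensemble
module's robustness checks are the model's answer to that variability, not
a replacement for it.

## Problem sizes

All headline computations are desk-scale: a single trajectory integrates in
well under a second at 1001 output samples; the two-bleb coarsening run
(60 min simulated) takes a couple of seconds; the 100-draw dynamics and
500-draw steady ensembles complete in about a minute together. These sizes
match the protocols the model was built to reproduce and are the ones used
by the test suite and the acceptance script.
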