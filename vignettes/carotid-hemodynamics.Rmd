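---
title: "Pulsatile non-Newtonian hemodynamics in an idealized carotid bifurcation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsatile non-Newtonian hemodynamics in an idealized carotid bifurcation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidflow)
```

## The problem

The common carotid artery (CCA) splits into the internal (ICA) and
external (ECA) carotid arteries. The wall shear stress (WSS) that
pulsatile blood flow exerts around this bifurcation is a recognized
correlate of atherosclerotic plaque formation, and blood rheology —
driven chiefly by hematocrit — modulates it. `carotidflow` simulates
pulsatile, incompressible, shear-thinning blood flow through an
idealized carotid bifurcation for four blood conditions (anemic,
diabetic, and two healthy parameter sets), and post-processes wall
shear stress, skin friction, strain rate, a wall-deformation surrogate,
and plane-wise statistics, ending in a comparative high/average/low
ranking of the blood types.

## Constitutive model

Blood viscosity follows the four-parameter Carreau law

$$\mu_{\mathrm{eff}}(\dot\gamma) \;=\; \mu_\infty + (\mu_0-\mu_\infty)
\left[1+(\lambda\dot\gamma)^2\right]^{\frac{n-1}{2}},$$

where $\dot\gamma = \sqrt{2\,D\!:\!D}$ is the generalized shear rate of
the rate-of-deformation tensor $D$. The four registered cases are
hematocrit-matched experimental fits:

```{r}
do.call(rbind, lapply(blood_case_names(), function(nm) {
  b <- load_blood_case(nm)
  data.frame(case = nm, n = b$carreau$n, lambda_s = b$carreau$lambda_time,
             mu_inf = b$carreau$mu_inf, mu_0 = b$carreau$mu_0,
             hematocrit = b$hematocrit)
}))
```

All four sets are shear-thinning ($n<1$); the constructor rejects
$n>1$. At physiological shear ($\dot\gamma \approx 100\,\mathrm{s^{-1}}$)
the effective viscosities order with hematocrit — diabetic (65%) above
both healthy sets (≈45%) above anemic (25%):

```{r}
viscosity_ordering(lapply(blood_case_names(), load_blood_case), 100)
```

The two healthy parameter sets come from different experimental sources
and differ strongly in their zero-shear plateau (0.0161 vs 0.056 Pa s);
both are kept verbatim, which is why they are carried as separate
cases. Mass density is not part of the published parameter sets; the
standard whole-blood value $\rho = 1060\ \mathrm{kg\,m^{-3}}$ is used
for every case and is overridable per case. Inside the solver the
viscosity is evaluated with a shear-rate floor
($\dot\gamma_{\min}=10^{-6}\,\mathrm{s^{-1}}$, configurable) so the
flat zero-shear plateau cannot stall the nonlinear iteration.

## Boundary conditions

The inlet velocity is the piecewise cardiac waveform at 120 bpm
(period $T = 60/120 = 0.5$ s),

$$v_{\mathrm{in}}(t') = \begin{cases}
0.5\,\sin[4\pi(t'+0.0160236)] & 0 < t' \le 0.218\,\mathrm{s}\\
0.1 & 0.218 < t' \le 0.5\,\mathrm{s}
\end{cases}$$

with $t' = t \bmod T$: a sinusoidal systole peaking at 0.5 m/s followed
by a 0.1 m/s diastolic plateau. The phase offset makes the systolic
onset continuous to $10^{-4}$ m/s; at the systole-to-diastole joint the
sine re-enters the plateau with a residual jump of about
$2.9\times10^{-4}$ m/s, so the waveform's true minimum is 0.09971 m/s
rather than exactly 0.1. The constructor therefore verifies joint
continuity at a $10^{-3}$ m/s tolerance, and tests compare the minimum
to 0.1 at that precision.

The profile is applied as a spatially uniform (plug) inlet by default —
no radial inlet shape is part of the model statement — with a
parabolic equal-mean alternative and arbitrary `function(y, t)`
profiles available (the analytic-oracle tests use the latter). Both
outlets carry a constant static gauge pressure of 100 mmHg
$\approx 13332$ Pa (the mean of typical 120/80 mmHg systolic/diastolic
pressures); it is held constant in time, and no windkessel or
prescribed ICA/ECA flow split is imposed — the split emerges from the
pressure boundary conditions.

## Geometry and meshes

The published study used an unpublished patient-like 3D surface whose
radii and branch angles are not stated, so absolute field magnitudes
from that geometry cannot be matched — only closed-form quantities and
trends. `carotidflow` instead provides a parametric reduced geometry
with two mesh modes:

* **Axisymmetric tube** (radius `r_cca`): exact analytic solutions
  exist (Poiseuille, power-law, Womersley), making this the
  verification workhorse and the cleanest setting for rheology
  comparisons.
* **Planar Y-bifurcation**: channel widths equal to the vessel
  diameters, a linear flare from the CCA mouth into the two diverging
  branch channels (ICA wider than ECA, default 25° branch angles), on
  a Cartesian grid with staircase-masked walls.

Defaults (`r_cca` 3.1 mm, `r_ica` 2.2 mm, `r_eca` 1.7 mm) are typical
adult carotid dimensions; every value is overridable. The axial
coordinate is anchored at the bifurcation apex: the 30 analysis planes
run from plane 1 at −31 mm through plane 16 at 0 mm to plane 30 at
+18 mm, uniformly spaced within each segment (only the three anchors
are prescribed; uniform spacing is the package's choice). Planes 21–30
cut both branches and their statistics pool the two.

Cells are uniform squares of the requested size. An optional coarser
axial spacing is available for streamwise-invariant verification runs.
Boundary faces are tagged uniquely (`inlet`, `outlet1` = ICA,
`outlet2` = ECA, `wall`, `axis`), and each fluid cell records its
distance to the nearest wall face for the deformation surrogate.

## Flow solver

The solver integrates the incompressible momentum balance
$\rho(\partial_t \mathbf v + \mathbf v\cdot\nabla\mathbf v) =
-\nabla p + \nabla\cdot(\mu_{\mathrm{eff}}\nabla\mathbf v)$ with
$\nabla\cdot\mathbf v = 0$ on a staggered (MAC) grid — velocities on
faces, pressure at cell centres — which avoids pressure
checkerboarding. Each step is an incremental Chorin-style projection:

1. effective viscosity from the current strain-rate field
   (Picard-lagged; one sweep per step by default, more when
   `max_inner_iters > 1` until `picard_tol` is met);
2. implicit momentum predictor with first-order upwind advection and
   variable-viscosity diffusion, inlet Dirichlet velocity at $t+\Delta t$
   and no-slip walls;
3. pressure-Poisson solve (sparse Cholesky, factorized once per mesh)
   with the outlet gauge pressure as Dirichlet value;
4. velocity correction to discrete divergence-freeness.

Advection is treated *implicitly* rather than explicitly: the cardiac
marching schedule ($\Delta t = 0.008$ s over 50 steps) corresponds to
an advective CFL number of 10–20 on sub-millimetre cells, which no
explicit scheme survives. The implicit upwind operator is
unconditionally stable and keeps the matrix an M-matrix; the price is
first-order accuracy in time and added upwind diffusion, which the
time-step-sensitivity harness quantifies. A finite `cfl_limit` can be
set as an accuracy guard, in which case `advance()` refuses an
over-long step and names the admissible one; it is disabled (`Inf`) by
default.

The initial condition is rest (zero velocity, pressure equal to the
outlet gauge value); the waveform itself ramps the inflow over the
first systole. Body force defaults to zero (gravity neglected). Runs
are fully deterministic: two identical configurations produce bitwise
identical fields.

### Verification against analytic oracles

Three closed-form solutions exercise the three nontrivial ingredients:

* steady Newtonian tube flow vs the Poiseuille parabola (centreline
  within 2%, wall shear within 5% on a 20-radial-cell mesh, with
  second-order convergence under refinement);
* steady shear-thinning flow vs the power-law pipe profile
  $u(r) = \frac{n}{n+1}(GR/2K)^{1/n} R\,[1-(r/R)^{(n+1)/n}]$
  (within 3%), exercising the variable-viscosity momentum balance;
* pulsatile Newtonian flow vs the Womersley series (within 5% RMS over
  a cycle at Womersley number $\alpha = 3$), exercising the
  time-dependent projection. The complex-argument Bessel function
  $J_0$ in the series is evaluated by its power series, accurate for
  the moderate $\alpha \lesssim 15$ of arterial flow, with a
  closed-form quasi-steady branch below $\alpha = 10^{-3}$.

Mass conservation is structural: the projection enforces a discrete
divergence below $10\times$ the pressure tolerance in every cell, so
the inlet flux balances the two outlet fluxes to round-off at every
step.

## Post-processing

* **Wall shear stress**: $\tau = \mu_{\mathrm{eff}}\,|\partial u_t/
  \partial n|$ at each lateral wall face, one-sided over the half-cell
  between the no-slip wall and the adjacent cell centre; reported as a
  non-negative magnitude. On staircase walls the wall-normal direction
  is taken per face.
* **Skin friction**: $C_f = \tau / (\tfrac12\rho v_{\mathrm{ref}}^2)$
  with $\rho = 1060$ kg/m³ and $v_{\mathrm{ref}} = 0.1$ m/s (the
  diastolic/characteristic inlet velocity). This pair reproduces the
  published worked example $\tau_{\max} = 7.18665\ \mathrm{Pa}
  \rightarrow C_{f,\max} = 1.35593$ to within $10^{-3}$ relative.
  Both references are configurable.
* **Wall-deformation surrogate**: the product
  $(\dot\gamma\,\Delta t)\times\delta_{\mathrm{wall}}$ of the per-step
  strain and the cell-to-wall distance. This follows the stated
  strain-times-distance rule of the original fluid–structure
  procedure, but note that rule does **not** numerically reproduce the
  deformation values printed alongside it (average strain 75.6475 ×
  average distance 0.0011427 gives 0.0864, not the printed 0.0346), so
  the surrogate is documented as a relative indicator with the product
  contract tested, and is never asserted against published deformation
  magnitudes. It is not a structural displacement.
* **Plane statistics**: min/avg/max of velocity magnitude, pressure,
  strain rate and deformation over the cells each plane cuts, and of
  WSS/$C_f$ over the wall faces nearest the plane (nearest-plane
  assignment by axial coordinate).
* **Ranking**: per quantity (velocity, pressure, wall shear, strain
  rate) and statistic (min/avg/max), cases are labelled by tertile of
  the fractional rank $(p-\tfrac12)/k$: top third "high", bottom third
  "low". Tied values share the higher label; an all-tied set is
  labelled "average" throughout.

## The comparative study

`run_study()` shares one mesh, solver configuration and boundary set
across the blood cases, so result differences isolate the rheology.
Under equal inflow the diabetic case — the most viscous at every shear
rate — necessarily produces the largest inlet-to-outlet pressure drop,
and in the tube it also carries the largest mean wall shear (mean WSS
is proportional to the mean axial pressure gradient there). Both
healthy cases transport more velocity per unit pressure drop than the
diabetic case. These forced orderings are the package's desk-scale
stand-in for the published comparative table and are what the
acceptance suite asserts.

On the planar bifurcation the computed ranking can differ from
comparative tables obtained with full 3D fluid–structure simulations;
in particular, anemic blood (lowest viscosity) shows the *lowest*
pressure drop here under equal inflow, whereas published comparative
tables list anemic pressure and wall shear as "high". With a fixed
flow rate, pressure drop is monotone in viscosity — the package
reports its own computed ranking and does not force agreement.

## Sensitivity harnesses

`grid_independence()` re-solves on a descending ladder of cell sizes
and `timestep_sensitivity()` on a list of `(dt, n_steps)` plans,
tracking average outlet velocity, average and maximum WSS, and average
deformation. The published procedure reports such ladders graphically
without a numeric criterion; the package uses an explicit rule —
select the coarsest level whose change to the next-finer level is
below a 2% default tolerance for all metrics, falling back to the
finest level with a non-convergence flag. Time-step plans are compared
at the latest common time (the published step ladders imply
inconsistent horizons, which are deliberately not reproduced); no plan
is auto-selected unless a tolerance is supplied, mirroring the
qualitative original choice.

## Numerical choices and problem sizes

* Pressure Poisson: direct sparse Cholesky, so the divergence bound
  ($10\times$ `poisson_tol`, default $10^{-7}\,\mathrm{s^{-1}}$) holds
  with orders of magnitude to spare.
* Momentum: sparse LU per step (systems of a few thousand unknowns).
* Degenerate inputs: zero inflow is a fixed point to round-off;
  `advance` validates CFL only when a finite limit is set; meshes
  refuse cells larger than the smallest vessel radius.
* The documented studies run at desk scale by design: verification
  meshes of 10–24 radial cells (≈500–10 000 fluid cells), cardiac runs
  of 50 steps at $\Delta t = 0.008$ s, Womersley runs of 3 cycles at
  200 steps per cycle. These sizes keep the full verification suite in
  the half-minute range on one core while leaving every tolerance met
  with margin; all of them are configuration values, not limits.

## Limitations

* Rigid walls: the two-way fluid–structure interaction of the original
  study is replaced by the strain-times-distance surrogate above.
* Reduced dimensionality: axisymmetric or planar; no 3D tetrahedral
  solve, no patient-specific segmentation. Staircase walls blur local
  WSS extrema near the apex, so bifurcation-mode WSS is meaningful as
  a trend, not pointwise.
* Laminar flow only (peak Reynolds number ≈ a few hundred; no
  turbulence model), Newtonian-plus-Carreau rheology only (no
  yield-stress models), and no oscillatory-shear-index or
  time-averaged WSS maps.
* Passing the analytic-oracle and trend tests demonstrates correct
  solver physics on the reduced geometries; it does not certify
  patient-specific magnitudes, which depend on the true 3D geometry.
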