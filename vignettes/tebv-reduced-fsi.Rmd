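---
title: "A reduced-order FSI model of a perfused tissue-engineered vessel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order FSI model of a perfused tissue-engineered vessel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tebvflow)
```

## The system being modelled

A tissue-engineered blood vessel (TEBV) — a cell-seeded hydrogel tube with a
2.0 mm inner and 5.0 mm outer diameter — is sutured into a microfluidic
perfusion chamber and driven by a peristaltic pump at a nominal 500 uL/min
with a 1 Hz pulse. A pressure sensor at the outlet reads 640–780 Pa over the
cycle. The vessel wall is soft (tens of kPa), so the lumen visibly dilates
and relaxes with each pulse. The package models this system end to end:

1. **materials** — reduce uniaxial tensile tests on dog-bone specimens to
   stress–stretch curves and fit a linear (Hookean) wall modulus;
2. **rheology** — fit a shear-thinning power-law viscosity to rheometer
   sweeps of the culture media;
3. **solver** — simulate pulsatile perfusion of the compliant tube with a
   one-dimensional fluid–structure interaction (FSI) model;
4. **comparison** — quantify agreement with the measured diameter waveform,
   flow rate and tracked cell-cluster velocities;
5. **synthetic data** — generate every bench measurement the pipeline
   consumes, with seeded noise, so the whole chain is testable offline.

## Wall mechanics

### Stress–stretch reduction and the Hookean fit

Tensile records are reduced pointwise to stretch $\lambda = L/L_0$ and
engineering stress $\sigma = F/(D\,h)$, with the specimen thickness $h$
taken as the mean of the per-location readings. The wall model is linear:
`fit_hookean()` regresses stress on either the stretch itself
(`stretch_linear`, the form $\sigma = E\lambda$; the default) or on the
engineering strain $\lambda - 1$ (`strain_linear`). With an intercept these
are the same least-squares problem re-parameterised — identical fitted
values and slope, different intercept — so the choice only matters when the
intercept is suppressed. Both behaviours are exposed because the bench
protocol this emulates fitted "$\sigma = E\lambda$" without stating whether
an intercept was used; the default is the literal reading
(`stretch_linear`, intercept on) with the conventional alternative a
keyword away.

### The thick-walled cylinder (Lamé) solution

For a linear-elastic cylinder with inner radius $a$, outer radius $b$,
internal pressure $p_{in}$ and external pressure $p_{out}$:

$$\sigma_{rr}(r) = \frac{p_{in}a^2 - p_{out}b^2}{b^2-a^2}
 - \frac{(p_{in}-p_{out})a^2b^2}{(b^2-a^2)\,r^2},\qquad
\sigma_{\theta\theta}(r) = \frac{p_{in}a^2 - p_{out}b^2}{b^2-a^2}
 + \frac{(p_{in}-p_{out})a^2b^2}{(b^2-a^2)\,r^2}$$

with the plane-strain radial displacement

$$u(r) = \frac{1+\nu}{E}\left[(1-2\nu)\,
 \frac{(p_{in}a^2-p_{out}b^2)\,r}{b^2-a^2}
 + \frac{(p_{in}-p_{out})a^2b^2}{(b^2-a^2)\,r}\right].$$

`lame_solution()` evaluates the full field (tests verify the traction
boundary conditions exactly and radial equilibrium to second order under
grid refinement); its inner-surface slope $C = u(a)/p_{in}$,

$$C = \frac{a(1+\nu)\left[(1-2\nu)a^2 + b^2\right]}{E\,(b^2-a^2)},$$

is the *tube-law compliance* that closes the flow model. Plane strain is
the default regime — the vessel is long and held at both ends by sutures —
with plane stress available for unconstrained rings. The Poisson ratio is
not measurable from a uniaxial test alone; the default $\nu = 0.45$ treats
the hydrogel as nearly incompressible and is configurable.

## Rheology

The culture media is shear thinning. The rheometer sweep (1–1000 s$^{-1}$)
is fitted on the log scale, $\log\mu = \log K + n\log\dot\gamma$, giving a
consistency $K$ in cP and exponent $n < 0$; equivalently
$\tau = K\dot\gamma^{\,m}$ with flow-behaviour index $m = n+1$. The fit is
performed on apparent viscosity rather than on shear stress: a consistency
printed in centipoise with $n \approx -0.22$ is only dimensionally coherent
as a viscosity law (the stress form with the same constants would be
shear-thickening). The stress-form constants are recorded alongside in the
JSON report. Outside the calibrated window the viscosity is clamped to its
boundary value so $\mu$ stays bounded as $\dot\gamma\to 0$; the clamp keeps
the law continuous and monotone.

## The reduced FSI solver

### Governing equations

The full problem is three-dimensional: Navier–Stokes in a moving lumen
coupled to an elastic wall through interface tractions. At these scales —
centimetre tube, millimetre bore, mm/s velocities, Reynolds number of order
one, pulse wavelength far longer than the segment — the flow is laminar and
essentially unidirectional, and the wall responds quasi-statically. The
package therefore solves the section-averaged (one-dimensional) reduction:

$$\frac{\partial A}{\partial t} + \frac{\partial Q}{\partial x} = 0,\qquad
\frac{\partial Q}{\partial t}
 + \frac{\partial}{\partial x}\!\left(\alpha\frac{Q^2}{A}\right)
 + \frac{A}{\rho}\frac{\partial p}{\partial x}
 = \frac{2\pi R}{\rho}\,\tau_w,$$

where $A(x,t)$ is the lumen area, $Q(x,t)$ the flow rate,
$R = \sqrt{A/\pi}$, and the moving-mesh and interface-traction terms of the
3D formulation are absorbed into the area equation and the tube-law
closure $p = p_{ext} + (\sqrt{A/\pi} - a)/C$. The wall friction closure is
the fully developed power-law value

$$\tau_w = K_{SI}\left[\frac{3m+1}{4m}\frac{8V}{D}\right]^m,\qquad V = Q/A,$$

which reduces to the Poiseuille $8\mu V/D$ at $m=1$, and the momentum
correction $\alpha$ is obtained by numerical quadrature of the
reconstructed power-law profile

$$u(r) = V\,\frac{3m+1}{m+1}\left[1 - (r/R)^{(m+1)/m}\right]$$

(4/3 for a parabola; a fixed value can be supplied instead). The same
profile reconstructs point velocities for the cell-cluster comparison; its
area average equals $V$ identically and its wall gradient reproduces
$\tau_w$, so the closures are mutually consistent (tested to 1%).

Boundary conditions follow the bench setup: a prescribed velocity waveform
at the inlet, $Q(0,t) = U(t)\,A(0,t)$, and the measured pressure waveform
at the outlet, $p(L,t) = p_{out}(t)$. A pressure-inlet mode is retained as
an option because the two descriptions of the source experiment disagree on
which quantity the inlet carries; the flow-rate reading is the default
since the pump is a positive-displacement device. The inlet waveform family
is an offset sinusoid $U(t) = \bar U\,[1 + (PI/2)\sin(2\pi t/T)]$ with
pulsatility index $PI = 1$ by default (the published pump waveform is not
available in tabulated form; the family and its parameters are config
options, and a skewed-pulse alternative is provided). The outlet phase
relative to the inlet is unstated in the source and defaults to in-phase.

### Discretisation and numerical choices

* **Staggered finite volumes**: areas live on $N$ cells, flow rates on the
  $N+1$ faces. Mass conservation is then exact in the discrete sense — the
  measured cycle imbalance in the default run is at rounding level.
* **IMEX $\theta$-scheme**: the stiff pressure and friction terms are
  implicit ($\theta = 0.6$), advection explicit. The tube makes the system
  acoustically stiff — the pulse-wave speed $c=\sqrt{r/(2\rho C)}\approx
  2.9$ m/s puts the acoustic CFL limit near $10^{-4}$ s — while the
  physically interesting dynamics are at 1 Hz. The implicit treatment lets
  the solver run at the protocol time step of 0.01 s; an advective CFL
  guard halves the step (with a warning) in the rare case mean-flow
  advection approaches the grid speed.
* **Newton iteration** with an analytic Jacobian solves each implicit step;
  convergence is declared on the relative step norm ($10^{-10}$), which
  remains meaningful in the rigid-wall limit where residual scales span
  many orders of magnitude. Steps that would drive the area negative are
  damped and, failing that, raise a stability error advising a smaller
  step.
* **Friction smoothing**: $|\dot\gamma|^{m}$ has an unbounded derivative at
  zero flow for $m<1$; the implemented law
  $K\dot\gamma(\dot\gamma^2+\varepsilon^2)^{(m-1)/2}$ with
  $\varepsilon = 10^{-9}\,\mathrm{s}^{-1}$ is smooth at the origin and
  indistinguishable from the exact law at any resolvable shear rate.
* **Periodicity**: whole cycles are run until the monitor-section diameter
  waveform changes by less than $10^{-5}$ (relative L2) between cycles;
  the following cycle is recorded. The system is strongly damped (friction
  relaxation ~0.02 s), so this typically takes 3 cycles.
* **Mesh refinement**: `refine_until_converged()` raises the cell count by
  10% per step (shrinking the time step proportionally) until the
  diameter-*expansion* waveform changes by less than 2% in L2. The
  expansion $d(t) - 2a$ is used rather than the raw diameter because the
  latter is dominated by its 2 mm baseline and would satisfy any tolerance
  at any resolution.
* **Monitor section**: the axial midpoint by default.

The default resolution is 33 cells and $\Delta t = 0.01$ s; the oracle
tests (steady power-law pressure drop, hydrostatic relaxation, rigid and
compliance limits) run at 17 cells, where they already pass their 1%
tolerances. A single refinement confirms grid independence of the default
configuration.

### Post-processing

The wall is quasi-static: at each recorded instant the Lamé field is
evaluated at the local lumen pressure, giving hoop/radial stress and strain
across the wall. Under internal pressurisation the maximum principal
stress is the inner-surface hoop stress. Wall shear stress series come from
the friction closure at the monitor section.

## Comparison with measurements

`expansion_error()` registers simulated and measured diameter waveforms on
a common uniform grid over one period (periodic linear interpolation),
phase-aligns them by circular cross-correlation — the registration used in
the source figure is unstated, and a deliberate shift is recovered by the
tests to the grid resolution — and reports per-time relative errors of the
*expansion from baseline*, $e(t) = |\Delta d_{sim} - \Delta
d_{exp}|/|\Delta d_{exp}|$, with the measured expansion as denominator
(this convention reproduces the worked 0.18 vs 0.14 mm $\to$ 28.6%
example). Instants where the measured expansion is below 5% of its peak are
excluded: a relative error against a vanishing denominator is noise, and
the floor makes the summary statistics stable (the fraction excluded is
reported). Cluster velocities are per-track least-squares slopes of
position against time — robust to frame jitter, exact on clean linear
tracks — summarised as mean ± sample SD. The flow-rate check uses the
nominal set point as denominator.

## What the synthetic generator does and does not emulate

One seeded configuration (`synth_config()`) drives every stream through
independent substreams, so a stage can be regenerated without disturbing
the others; identical configurations give byte-identical CSVs. Noise
models are package inventions chosen to match the printed experimental
scatter in magnitude: multiplicative Gaussian on tensile strain (CV 1%),
log-normal on viscosity (log-SD 0.02), Gaussian on diameter (10 µm) and
sensor pressure (5 Pa). Tensile generation inverts the strain form
$\lambda = 1+\sigma/E$, which is physically invertible at zero force; both
fit parameterisations recover $E$ from it exactly in the noise-free limit.

Cell clusters get radial positions from a configurable law —
`uniform_area` (unbiased), `uniform_radius` (oversamples the fast core;
mean $4V/3$ under a parabolic profile), `near_wall` (outer 15% of the
radius; always understates the mean) — and are advected at the local
profile velocity. The real microscope's focal-plane sampling law is
unknown, so no default is claimed to match the bench measurement; the
ordering of the biases is the reproducible property. One practical caveat
the tests account for: a slope fitted over a *single* period carries a
phase bias of a few percent from the periodic component of the
displacement (it decays roughly as $1/W^2$ with $W$ observed periods), so
the identity "area-uniform tracked mean $\approx$ section mean" is tested
over four periods while the generator's default remains the bench
condition of one recorded period.

What is *not* emulated: microscope images or video (tracks and diameters
are consumed as tables), cluster entry/exit from the field of view, focal
blur, wall-collision dynamics, and any systematic sensor drift. Passing
tests therefore demonstrate the pipeline's internal consistency and its
statistical behaviour under the assumed noise — not the fidelity of those
noise models to any particular instrument.

## Known limitations

* The 1D reduction cannot represent three-dimensional entrance effects,
  secondary flows, or axially varying wall properties; its diameter
  dynamics follow the outlet pressure almost quasi-statically because the
  friction pressure drop across 20 mm is only a few Pa.
* The linearised tube law is accurate for the ~5% radial strains seen here
  but would misrepresent large distensions or collapse ($p$ well below
  $p_{ext}$).
* The Hookean wall and power-law fluid are calibration-range models:
  extrapolation beyond $\lambda \approx 1.35$ or outside 1–1000 s$^{-1}$
  inherits no data.
* Wave reflections from downstream tubing, gravity, and wall inertia are
  neglected (the latter is justified at sub-kPa pressures and mm/s
  velocities).

## Reproducing the chain

```{r, eval = FALSE}
library(tebvflow)
res <- run_pipeline(seed = 1, verbose = TRUE)
print(res)
autoplot(res$simulation)
```

`scripts/acceptance.R` in the source repository recomputes the headline
quantities (modulus summary, worked comparison examples, calibration
recovery, simulation summaries and oracle errors) from scratch and writes
them as JSON.
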