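---
title: "Models and methods behind littsim"
author: "littsim maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind littsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(littsim)
```

littsim is a desk-scale simulator of MR-guided laser interstitial thermal
therapy (MRgLITT) of brain tumors, with an automated treatment controller:
a PID loop regulates the tumor-boundary temperature and a fuzzy-logic stage
controller retracts the laser probe in 5 mm increments on thermal-damage
feedback. This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic phantoms can show.

## Bioheat model

Tissue temperature follows the modified Pennes equation

$$\rho_i C_{p,i}\frac{\partial T}{\partial t}
  = \nabla\!\cdot\!(k_i \nabla T)
  + \rho_b C_{p,b}\,\omega_{b,i}\,(T_b - T)
  + Q_\mathrm{laser} + Q_\mathrm{met,i},$$

per tissue domain $i$ (skull, general CSF, brain, CSF ventricles, tumor).
Brain and tumor conductivity and heat capacity grow exponentially with
temperature, $k(T) = k_0\,e^{c_k (T-37)}$ with $c_k = c_C =
0.002\,\mathrm{K^{-1}}$ by default, and are frozen at their 90 °C value
above 90 °C — the vaporization-regime *decrease* of thermal properties is
deliberately not modeled. Skull and CSF have constant properties. CSF
conductivity carries a convective-enhancement multiplier (default 10, a
Nusselt-style surrogate for unresolved CSF convection). Blood enters with
$\rho_b = 1050$, $C_{p,b} = 3617$, $T_b = 37$ °C. All material values in
`default_materials()` are representative literature figures and are
configuration, not measurements.

Boundary conditions are Robin (third-kind): $h = 5\ \mathrm{W/(m^2 K)}$ to
a 20 °C room on the skull surface, and $h = 100\ \mathrm{W/(m^2 K)}$ to
20 °C coolant on the catheter wall — applied only on lumen faces adjacent
to the active 5 mm tip; the shaft above the tip is adiabatic (a modeling
choice; conjugate heat transfer in the coolant channel is out of scope).
Everything starts at 37 °C.

### Discretization

The solver is a conservative finite-volume scheme on structured grids,
expressed on a face graph (cells, interior faces with harmonic-mean
conductances, boundary faces with film coefficients). Two geometries share
the same stepping code: the default axisymmetric $r$–$z$ half-plane (the
probe on the axis of a spherical tumor makes the whole setup
axisymmetric, at a fraction of the 3-D cost) and a 3-D Cartesian mode for
NIfTI label maps. Time stepping is implicit BDF2 with a fixed
$\Delta t = 1$ s (bootstrapped by one backward-Euler step), matching the
1 s cadence of clinical MR thermometry; backward Euler is available. The
nonlinear property dependence is lagged one step (a single Picard
iteration), which at $\Delta t = 1$ s changes temperatures by far less
than the property uncertainty. Because the discretization is conservative,
the per-step energy budget (storage = boundary + perfusion + laser +
metabolism) closes to round-off under backward Euler; the test suite
asserts closure to 0.5 %.

### Verification

`verify_solver()` runs the same stepping code on a fine 1-D spherically
symmetric grid ($\Delta r = 0.1$ mm, shells out to 150 mm) with a constant
point source deposited in the innermost shell, and compares the steady
state against the closed form
$T(r) = T_b + P\,e^{-\lambda r}/(4\pi k r)$,
$\lambda = \sqrt{\omega_b \rho_b C_{p,b}/k}$. Two numerical choices
deserve a note. First, the volumetric heat capacity of the verification
medium is set small ($10^5\ \mathrm{J\,m^{-3}K^{-1}}$): the steady profile
is independent of it, and the transient then decays in a few hundred 1 s
steps instead of hours. Second, the outer face is pinned at the *analytic*
value at the domain radius rather than at $T_b$; for perfused media the
two agree to $10^{-5}$, and the zero-perfusion (pure $1/r$) limit stays
exact on a finite domain. The measured maximum relative error over
$r \in [3, 15]$ mm is 0.011 %, and halving $\Delta r$ reduces it about
fourfold (second order).

## Laser deposition

The single-optical-parameter model describes light with one effective
attenuation coefficient $\mu_\mathrm{eff}$ per tissue. Each point
sub-source of power $P_k$ deposits

$$Q(\mathbf{x}) = P_k\,\mu(\mathbf{x})\,
  \frac{e^{-\tau_k(\mathbf{x})}}{4\pi\,|\mathbf{x}-\mathbf{x}_k|^2},
  \qquad \tau_k(\mathbf{x}) = \int \mu\, ds,$$

with the optical depth accumulated by fixed-count midpoint sampling of
$\mu$ along the ray on the voxel grid. The kernel uses only
$\mu_\mathrm{eff}$ and conserves energy exactly in a homogeneous medium
(deposited power $P(1-e^{-\mu R})$ inside radius $R$); the whole-domain
deposited power never exceeds the source power, which the tests assert on
every configuration they touch. Cells within four grid spacings of a
sub-source are subsampled (16×16 in $r$–$z$ with ring-volume weights) to
control the $1/d^2$ quadrature error; in 3-D the cell containing the
source receives its analytic equal-volume-sphere absorption.

Two source models: PSLH (one point at the tip center) and DPHS ($N$
sub-sources spread over the 5 mm tip, $P/N$ each, $N=10$ by default);
$N = 1$ reduces DPHS to PSLH bit-identically. At the stage-1 boundary
probe the two agree within ~2.7 % in both temperature rise and damage,
which is why the point source is the default. Note the far-field
equivalence of the two models holds in the geometric sense only when
$\mu L \ll 1$; at tissue-like $\mu = 0.35\,\mathrm{mm^{-1}}$ the
exponential path-length differences across the tip dominate, so the
equivalence test in the suite uses a weakly absorbing medium.

Damage-dependent optics ("vop" mode) interpolate linearly between native
and coagulated attenuation, $\mu = \mu_n (1 + \Omega\,(f_c - 1))$ with
coagulation factor $f_c = 1.5$. The deposition field is recomputed only
when the attenuation field has drifted by more than 1 % anywhere (or the
tip moved); the threshold is configurable down to every-step. Runs with
different optical fields can be rescaled to a common *domain-deposited*
power via `scale_to_reference_deposition()` (normalizing deposited rather
than source power is a documented choice). The default
$\mu_\mathrm{eff} = 0.35\,\mathrm{mm^{-1}}$ for brain and tumor at 980 nm
is a placeholder consistent with diffusion-theory estimates; skull and CSF
deposition is off by default. Override these for any quantitative claim
about real tissue.

## Thermal damage

Arrhenius first-order kinetics: the damage integral accumulates at rate
$A\,e^{-E_a/(R T_K)}$ (trapezoid rule in time, second order, exact for
constant temperature; a rectangle rule exists for cross-checks). The
damage *fraction* $\Omega = 1 - e^{-\alpha}$ is the modeled cell-death
fraction, so $1-\Omega$ is the survival probability and the clinical
retraction threshold $\Omega \ge 0.99$ is exactly
$\alpha \ge -\ln 0.01 = 4.605$. The default kinetic pair is the classical
Henriques protein-coagulation set $A = 3.1\times10^{98}\,\mathrm{s^{-1}}$,
$E_a = 6.28\times10^{5}\,\mathrm{J\,mol^{-1}}$, chosen because the model
requires negligible baseline damage at body temperature (with these
constants $\alpha \approx 3\times10^{-5}$ over 600 s at 37 °C); lower
activation-energy pairs in circulation accumulate appreciable spurious
damage at baseline, which would corrupt lesion-coverage metrics over long
treatments. Damage predictions are sharply sensitive to $E_a$, which is
why it is exposed in configuration.

Perfusion shuts down with damage: the perfusion rate in the tumor and in a
peritumoral brain margin is multiplied by $1-\Omega$. The margin width is
not constrained by data; 5 mm is a documented default.

## Phantoms and virtual MRTi probes

`build_concentric_phantom()` is a synthetic stand-in for a segmented
patient head: a spherical tumor (default radius 10 mm) inside concentric
brain (15 mm), general-CSF (3 mm) and skull (7 mm) shells, an optional
CSF-ventricle ring, and the probe lumen carved along the axis down to the
stage-1 tip. Shell thicknesses are configuration, not anatomy. Default
grid spacing is 0.5 mm, which puts at least three cells across the 1.65 mm
lumen diameter.

The controller reads virtual MR-thermometry voxels, volume-averaged like
the clinical imaging planes: per stage plane, a center probe (CP) annulus
hugging the lumen (inner diameter 1.65 mm, 1 mm wall, 3 mm height) and a
boundary probe (BP) cuboid (1×1×3 mm) touching the tumor boundary *from
inside* at radius $\sqrt{R^2 - z_j^2}$. In axisymmetric mode the BP cuboid
is represented by the ring $[r_b - 1\,\mathrm{mm}, r_b] \times
[z_j \pm 1.5\,\mathrm{mm}]$ intersected with the tumor; for an
axisymmetric field the ring average equals the cuboid average up to
$O(\Delta)$ — a documented approximation. Stage planes sit 5 mm apart
(the retraction increment), stage 1 deepest.

The bundled laser-log fixture (`make_fixture_log()`) emulates the *shape*
of a clinical pulsed treatment: three pulse trains (one per stage), short
8 W pulses (4 s on, 16 s off, six per stage) with two stepwise 5 mm
retractions, and ±1 s seed-controlled jitter. The short duty cycle is what
physicians use to stay clear of the 100 °C vaporization limit; since the
model has no vaporization physics to arrest runaway heating, a sustained
high-power log would produce unphysical temperatures rather than a
clinically shaped baseline.

## The cascaded controller

Per 1 s tick (controller period = solver step; an optional
`feedback_delay_steps` emulates the 5–7 s MRTi acquisition lag):

1. **Reference selection.** The regulated signal is the *hottest monitored
   boundary probe*, $\max_j T_{BP_j}$ over $j \le$ stage. This generalizes
   the clinical rule of holding to BP1 while it stays hotter than the
   newly active plane, protecting already-treated tissue.
2. **PID.** $U = K_p e + K_i \int e + K_d \dot e$ with $e = 60 - T_\text{ref}$
   and gains $K_p = 7.5$ W/K, $K_i = 0.5$ W/(K s), $K_d = 0$. $U$ is
   interpreted directly in watts and clamped to $[0, P_\text{max}]$
   ($P_\text{max} = 15$ W, a typical 980 nm system ceiling); a
   `normalized` mode (duty fraction times $P_\text{max}$) is available.
   Anti-windup is conditional integration — the accumulator freezes while
   the output is saturated in the direction the error would deepen — and
   the integral resets on each retraction, since retraction re-plants the
   loop. Both choices favor reproducibility over aggressiveness.
3. **Safety gate.** Power is forced to zero whenever any monitored CP
   reads $\ge 100$ °C, latched until all monitored CPs fall below 98 °C
   (2 °C hysteresis against chatter).
4. **Fuzzy retraction.** The active BP damage fraction is fuzzified with
   two membership functions — BELOW (trapezoid, certain below 0.95, zero
   at 0.98) and REACHED (ramp from 0 at 0.98 through 0.5 at 0.99 to 1) —
   and the rule base {REACHED ∧ stage < 3 → RETRACT; REACHED ∧ stage 3 →
   STOP; else HOLD} is defuzzified by maximum membership with a 0.5
   activation threshold. The shapes were designed so that the fired rule
   provably coincides with the crisp automaton "retract/stop iff
   $\Omega \ge 0.99$" (the suite sweeps 10⁴ points to confirm); a ramp
   saturating already at 0.99 would fire at 0.985 and break that
   equivalence. Only damage feeds the fuzzy layer (single-input design).

Outcome metrics: lesion coverage LC (percent tumor volume with
$\Omega \ge 0.99$, volume-weighted), per-probe milestones, total time,
delivered energy, maximum CP temperature.

## What the default study conditions actually do

Two findings from the default phantom are worth stating plainly, because
they bound what the controller can demonstrate there:

* **One-tick overshoot at the cap.** At 15 W the near-tip voxels heat at
  tens of K per second, so with 1 s sampling the on/off gate overshoots
  the 100 °C cap by ~13 K before it can react (maximum CP ≈ 112.7 °C).
  Holding a ±2 °C band at this power would need sub-second sampling or a
  power-limiting (rather than on/off) constraint handler.
* **Cap-limited regulation.** The gate's resulting ~1/6 duty cycle caps
  the average deliverable power near 2.5 W, while holding the 8.66 mm
  stage-1 boundary probe at 60 °C would need roughly 4 W. The reference
  therefore settles at a very steady 52.9 °C — the cap, not the PID,
  is the binding constraint on this geometry. Stage 1 still completes
  (damage integrates to 0.99 in ~30 min), but stage 2 regulates at
  50 °C and outlasts a 2 h clinical ceiling, so the default-phantom run
  reports itself incomplete. On smaller tumors (e.g. the 7 mm phantom in
  the README), boundary probes sit closer, the setpoint is reachable, and
  the full automaton — two 5 mm retractions, STOP, LC near 90 % against
  ~43 % for the pulsed baseline — plays out in a few minutes.

Passing tests on these phantoms therefore show that the physics engine is
verified against closed forms, that the controller logic implements its
specification exactly, and that automated damage-targeted dwell beats an
open-loop pulsed schedule on identical physics. They do not show that the
specific temperatures, times or coverages transfer to patient anatomy:
real geometry, patient-specific optical/kinetic parameters, MRTi noise and
lag, vaporization and charring are all outside the phantom.

## Uncertainty quantification

The optical parameters are the dominant unknowns. `litt_uq_study()` treats
the native and coagulated attenuation coefficients as independent uniform
variables (±20 % around nominal — placeholder ranges), with the
end-of-treatment BP damage fractions of a coarse-grid (1 mm) replay of the
pulsed fixture as quantities of interest. The pipeline mirrors the
surrogate-accelerated protocol: 20 Latin-hypercube training simulations
plus 10 held-out verification points; a total-degree-3 least-squares
Legendre polynomial surrogate (a deliberate simplification of adaptive
sparse polynomial chaos — the 0.001 relative tolerance and the 10-point
verification protocol are preserved, adaptive sparsity is not), rejected
in favor of the direct model if the held-out error exceeds tolerance; then
Saltelli sampling with Jansen estimators for first-order and total Sobol
indices *on the surrogate*, where evaluations are effectively free. The
base sample (default 32768) is sized so that doubling it changes every
index by well under 0.02 — the convergence criterion itself; at the
measured QoIs the doubling change is ~0.007. Monte-Carlo propagation
reports mean, SD, extremes, 10th/90th percentiles, 95 % bounds and the
surrogate verification error as the model error, and
`survival_normality_diagnostic()` checks the empirical pattern that
$\ln(1-\Omega)$ is approximately Gaussian while $\Omega$ is right-skewed.

On the coarse phantom the coagulated coefficient dominates the later-stage
boundary probes (first-order indices ~0.7 versus ~0.26 for the native
coefficient) with interaction shares below a few percent, reproducing the
qualitative published pattern: the near-tip core coagulates early, so most
of the variance in what reaches the boundary is carried by the coagulated
optics.

## Problem sizes and runtimes

Chosen as the package's own defaults: verification 1500 spherical shells;
default phantom ~7.5×10³ axisymmetric cells (0.5 mm); coarse UQ phantom
~1.9×10³ cells (1 mm); source-model comparison 240 s of constant-power
heating; UQ 20+10 simulator runs plus surrogate-side Saltelli designs;
controlled default run capped at 7200 s simulated. On one CPU the full
acceptance recomputation takes about six minutes and the test suite about
seven.

## Known limitations

No vaporization, charring or tissue shrinkage; no CSF flow (conjugate heat
transfer) — only enhanced conductivity; no MRTi noise model (the lag is an
optional delay only); no side-fire probes or probe rotation; the
multi-parameter ($\mu_a, \mu_s, g$) optical model is out of scope; the
axisymmetric BP ring is an $O(\Delta)$ stand-in for the clinical cuboid
voxel; all tissue parameters are population defaults, not estimates from
any patient.
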