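---
title: "Modelling particle sedimentation in a horizontal syringe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling particle sedimentation in a horizontal syringe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syrsed)
```

## The problem

Microfluidic and lab-on-chip experiments hold their sample — cells or
microparticles suspended in buffer — in a horizontal syringe driven by a
pump. Because the particles are denser than the buffer they settle, stick
to the barrel wall, and stop being deliverable: the *effective
concentration* $C_E(t)$ of the sample decays while the experiment runs.
`syrsed` quantifies this decay and its practical summary, the
*concentration half-life* $t_{1/2}$, three ways: closed form, by Lagrangian
particle tracking in a creeping-flow field, and from particle-counter
signal traces.

## The closed-form model

A sphere of radius $r_P$ and density $\rho_P$ in a buffer of density
$\rho_B$ and viscosity $\eta$ settles at the Stokes terminal velocity

$$v_T = \frac{2 g r_P^2 (\rho_B - \rho_P)}{9\eta},$$

signed negative downward for dense particles. The velocity relaxation time
$(2/9)\rho_P r_P^2/\eta$ is microseconds for micron-scale particles, so the
package advects particles inertialessly at the local fluid velocity plus
$v_T$ throughout.

Uniformly suspended particles translate rigidly downward, so in the barrel
cross-section (radius $R_S$) the region still occupied after a travelled
path $d_T = |v_T| t$ is the intersection of the disk with its own
translate — a two-circle lens. Two limiting regimes bound the effective
concentration ratio:

* **Upper boundary (lens / full cross-section)**: every suspended particle
  counts. $C_E/C_0$ is the lens area over $\pi R_S^2$; it reaches zero at
  $t = 2R_S/|v_T|$ and halves at $t_{1/2} \approx 0.8079\, R_S/|v_T|$. This
  is the high-flow-rate limit, where converging streamlines near the
  outlet lift particles from any cross-sectional position.
* **Lower boundary (circular segment / concentric outlet, no lift)**:
  particles below the outlet level can never leave, so only the segment
  above the descending depletion front counts, normalized by the initial
  half-disk. It reaches zero at $t = R_S/|v_T|$ and halves at
  $t_{1/2} \approx 0.4040\, R_S/|v_T|$.

Both curves share the profile $(2/\pi)(\arccos u - u\sqrt{1-u^2})$ in a
scaled time, so the upper coefficient is exactly twice the lower one;
`half_life_boundary_coefficients()` solves the profile for $1/2$ by
bisection on $[0,1]$ to $10^{-12}$ (the function is strictly decreasing
there, and bisection is robust at the endpoints where the derivative
vanishes). Real systems interpolate between the bounds:
$t_{1/2} = K_S R_S/|v_T|$ with an empirical sedimentation constant
$K_S \in [0.4, 0.8]$ that grows with flow-rate.
`fit_sedimentation_constant()` pools conditions and fits $K_S$ through the
origin (the model has no intercept; $R^2$ is computed against the
zero-intercept null, as `lm(y ~ 0 + x)` reports).

```{r bounds}
ps5 <- particle_spec(radius = 5e-6, density = 1070)   # 5 um polystyrene
syr <- syringe_spec(2.3e-3, 40e-3, 0.5e-3, 5e-3)      # 1 ml barrel
half_life_bounds(ps5, buffer_pbs(), syr)
```

### Numerical conventions

Arguments of $\arccos$ are clamped to $[-1, 1]$ and ratios to $[0, 1]$ to
absorb round-off; times past depletion return exactly 0. Matched densities
($v_T = 0$) are physically meaningful — no sedimentation — and return a
ratio of 1 for all times and infinite half-life bounds rather than an
error. Floating particles ($v_T > 0$) are handled through $|v_T|$: the
geometry is mirror-symmetric about the horizontal mid-plane.

### Parameter defaults

* $g = 9.81\ \mathrm{m/s^2}$, configurable via `model_constants()`.
* `buffer_pbs()`: $\rho_B = 1000\ \mathrm{kg/m^3}$, $\eta = 1$ mPa s. PBS
  density is rarely reported; the round value is within ~0.5% of water but
  the density *mismatch* $\rho_B-\rho_P$ enters $v_T$ linearly, so for
  near-neutral particles an accurate measured $\rho_B$ should be supplied.
* `buffer_water()`: water at 25 °C ($\rho_B = 997$, $\eta = 0.89$ mPa s),
  the working fluid of the flow simulations ("room temperature").

## The flow field

The bench-scale system is Stokes flow in a cylindrical barrel (radius
$R_S$, length $L_S$) closed by an end wall carrying a small outlet (radius
$R_O$, possibly offset vertically). Two backends implement it:

* **`superposition`** (default): Poiseuille flow in the bulk, blended over
  a smoothstep transition zone of length $2R_S$ upstream of the end wall
  into a half-space point sink of strength $Q$ at the outlet centre
  (magnitude $Q/2\pi r^2$, capped inside $r < R_O$ to remove the
  singularity). The Poiseuille amplitude is rescaled station-by-station so
  the net axial flux equals $Q$ through every cross-section (the sink's
  share is pre-integrated numerically and interpolated). This captures the
  two regimes the sedimentation model needs — parallel bulk flow and
  converging streamlines near the outlet — at negligible cost, and it
  supports eccentric outlets. Its known artifacts: the side-wall no-slip
  condition is satisfied only by the Poiseuille part (the sink adds a
  small slip there), and the end wall is not exactly impermeable, so a
  stray particle can strike it.
* **`stokes_axisym`**: a direct numerical solution of the axisymmetric
  stream-function equation $E^4\psi = 0$ on a 64 x 256 $(r,z)$ grid
  (second-order finite differences, coupled $E^2\psi = \chi$, $E^2\chi=0$
  system, sparse LU; no-slip walls via ghost-node relations, Poiseuille
  inlet, Poiseuille outflow through the hole). Concentric outlets only;
  it serves as the in-package validation of the superposition field. The
  linear system mixes scales badly ($O(1)$ Dirichlet rows against
  $O(1/\Delta r^2)$ stencil rows), so rows and columns are equilibrated
  before the solve.

Verified properties (see the test suite): flux constant in $z$ to 2%
(superposition, exactly flux-corrected by construction) and 0.5%
(stokes_axisym); wall speed < 1% of the mean axial velocity
(stokes_axisym); vertical velocity < 1% of the mean beyond $5 R_S$ from
the outlet — the regime where the closed-form boundary curves are exact.
The two backends agree on simulated half-lives to within a few percent at
the study conditions.

## The particle-tracking simulator

`run_simulation()` seeds 2,000 particles (the study default) uniformly in
the barrel volume, advects them with $\mathbf v_\mathrm{flow} + v_T
\hat{\mathbf y}$ (forward Euler at $dt = 0.05$ s by default; RK4
available — the fields are smooth and both agree, see tests), and applies
status transitions: *captured* when the particle centre reaches a wall
(particle radius neglected, $r_P \ll R_S$; no re-suspension), *exited*
when it crosses the outlet-entrance disk. The outlet tube itself is not
simulated; its transit is a constant delay. Particles do not interact or
alter the flow (loads of $10^6$/ml give an Einstein viscosity increment
below $10^{-3}$ mPa s — `einstein_viscosity_increment()`).

### Estimating the effective concentration from a simulation

Which observable of the particle cloud *is* the effective concentration?
This turns out to be the central design question, and the package exposes
three estimators because they genuinely measure different things:

1. **`suspended_fraction_curve()`** — the fraction of particles neither
   captured nor exited. With no flow this is exactly the lens (upper
   boundary) construction, and the test suite uses it as a Monte-Carlo
   oracle against the closed form.
2. **`exit_rate_curve()`** — binned outlet exits, normalized to the
   initial rate and smoothed: what a particle counter at the outlet
   records. At moderate and high flow-rates the capture funnel of the
   outlet (radius $r^* = \sqrt{Q/2\pi |v_T|}$) spans the cross-section and
   this tracks the bulk effective concentration. At very low flow-rates
   $r^* \ll R_S$: the outlet then samples the *local* concentration at
   nozzle height, which stays near $C_0$ until the depletion front has
   descended a full barrel radius — the rate curve stays flat long past
   the bulk half-life, and its event statistics are poor (few particles
   ever exit). This regime limitation is inherent to the observable, not
   to the simulation.
3. **`effective_fraction_curve()`** (default in `simulate_half_life()`) —
   snapshot counts of *deliverable* particles: suspended and either above
   the outlet level, or inside the lift zone where the vertical fluid
   velocity beats the settling speed ($v^y_\mathrm{flow} + v_T > 0$), or
   on a trajectory that in fact reaches the outlet (the simulator knows
   each particle's deterministic fate). The count is divided by the
   remaining sample volume fraction $1 - Qt/V_0$: physically the plunger
   advances and the sample column shortens, while the fixed simulation
   domain admits clean fluid instead — without the correction, drainage
   masquerades as concentration decay at high flow-rates.

The third estimator operationalizes "in suspension and able to reach the
outlet" directly. It reproduces the segment (lower-boundary) curve exactly
at $Q = 0$, uses the whole population (binomial noise on ~1,000 counted
particles, far tighter than outlet-event statistics), and yields a
sedimentation constant that increases monotonically with flow-rate —
$K_S \approx 0.42$ at 0.5 µl/min rising to $\approx 0.51$ at 50 µl/min for
5 µm polystyrene in the 2.2 mm barrel — consistent with the model's
interpolation between its bounds. It remains conservative at high
flow-rates (it does not reach the 0.8 lens bound, because particles below
the outlet level far upstream are counted only once their trajectory or
position qualifies). For top-eccentric outlets its accounting is harsh:
the deliverable region above a top-edge outlet is a thin sliver, so the
estimated half-life collapses — simulations of top outlets should be read
qualitatively only.

## The signal-analysis chain

The measurement emulated by `synthetic_data` and analysed by
`signal_analysis` is a laser particle counter: each transit produces a
pulse in a photodetector trace. The chain is
`lowpass()` (zero-phase 4th-order Butterworth, 100 Hz default — standard,
flat passband, no displacement of peak times) →
`detect_peaks()` (local maxima above median + 5 robust SDs, 1 ms
refractory; bench-scale defaults) → `bin_counts()` (1 s right-open
bins) → `normalize_and_smooth()` (divide by the mean rate over the first
20 s, 21-bin centred moving average) → `half_life_from_curve()` (first
0.5 crossing, linearly interpolated).

Two quantitative subtleties matter at realistic rates:

* **Pile-up.** The 100 Hz filter stretches sub-millisecond pulses to a few
  milliseconds; transits closer than that merge into one detected peak.
  The loss is proportional to the rate itself, which inflates the
  normalized curve late in the decay and biases the recovered half-life
  upward by ~8–12% at 20–40 events/s. `analyze_trace()` therefore applies
  the standard nonparalyzable dead-time correction
  $\lambda = m/(1 - m\tau)$, with $\tau$ estimated from the inter-event
  gap distribution (mean gap minus the memoryless exponential tail mean,
  median across blocks of 400 gaps; `estimate_dead_time()`). With the
  correction, recovery is unbiased (~+1% over 12 validation seeds), with
  a residual seed-to-seed scatter of about 5%; occasional seeds can still
  miss by more than 10%.
* **Normalization window.** The boundary curves are steepest at $t = 0$,
  so a long initial window under-measures the initial rate and delays the
  apparent crossing; the window (and all chain parameters) are
  configurable, and the normalization uses the *raw* corrected rate, not
  the smoothed one.

### The synthetic-trace generator

`synthetic_measurement()` turns any concentration curve into ground-truth
data: an inhomogeneous Poisson event train at $\lambda(t) = \text{rate}_0
\cdot C_E(t)/C_0$ (Lewis–Shedler thinning, seeded and isolated from the
global RNG), then Gaussian pulses (SD 0.5 ms, consistent with a ~100 µm
measurement region at mm/s channel velocities) of amplitude `snr` over
unit-variance Gaussian baseline noise at 10 kHz (a typical USB acquisition
card; the actual hardware rate is not critical). What it deliberately does
not emulate: optical scattering amplitude versus particle size, pulse
shape variation, doublets with correlated amplitudes, baseline drift.
Passing the round-trip tests therefore demonstrates the correctness of
the analysis chain's counting statistics, not robustness to every real
detector artifact.

## Study sizes used in tests and the acceptance script

Simulation checks run 2–3 pooled replicates of 2,000 particles at
$dt = 0.05$ s (the no-flow oracle uses $dt = 0.5$ s, where pure
translation makes the integrator exact), horizons of 600–1,500 s chosen
to cover the relevant half-lives, and snapshot spacing of 2 s for the
effective-fraction curves. Signal-chain validation uses traces of 650 s at
10 kHz, 40 events/s initial rate and SNR 8 across 3 seeds. These sizes
keep the full suite within a few minutes while leaving Monte-Carlo margins
(3 binomial SEs) comfortably wider than the observed deviations.

## Known limitations

* The superposition field is an approximation: no-slip is violated by the
  sink component at the side wall, and the end wall is slightly
  permeable; the `stokes_axisym` backend quantifies these errors for
  concentric geometries.
* Simulated half-lives at very low flow-rates sit near the analytic lower
  bound ($K_S \approx 0.40$–0.42), a little above finite-element values
  reported for comparable systems ($K_S \approx 0.35$); part of the gap
  is unstated fluid parameters in such comparisons, part is the estimator
  ambiguity discussed above.
* No Brownian motion, shear-induced migration, hindered settling,
  particle–particle interactions, non-spherical particles, or
  non-Newtonian buffers.
* The moving plunger is represented by a fixed domain with clean inflow
  plus the analytic volume correction, not by a deforming mesh; transient
  start-up of the pump is not modelled.
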