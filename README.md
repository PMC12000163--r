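# syrsed — particle sedimentation in horizontal syringes

Cells and microparticles loaded into a horizontal syringe settle while the
experiment runs: the density mismatch with the buffer drives them onto the
barrel wall, where they stick and stop being deliverable. For anyone
running microfluidics, flow cytometry, cell sorting or bioprinting from a
syringe pump, the practical question is *how long does my sample last* —
the concentration half-life `t_1/2` of the still-deliverable ("effective")
concentration.

`syrsed` answers it three ways:

* **Closed form.** A sphere settles at the Stokes terminal velocity
  `v_T = 2 g r_P^2 (rho_B - rho_P) / (9 eta)`. Uniformly suspended
  particles translate rigidly downward, so the occupied cross-section is a
  two-circle lens, and the effective concentration ratio is bounded by two
  analytic curves: the full-cross-section (lens) model, halving at
  `t_1/2 ≈ 0.81 R_S/|v_T|`, and the concentric-outlet no-lift (circular
  segment) model, halving at `t_1/2 ≈ 0.40 R_S/|v_T|`. Real systems fall
  in between: `t_1/2 = K_S R_S/|v_T|` with a flow-rate-dependent
  sedimentation constant `K_S ∈ [0.4, 0.8]`.
* **Lagrangian simulation.** 2,000 particles advected through a
  creeping-flow field of the barrel-plus-outlet geometry (a fast
  flux-corrected Poiseuille-plus-point-sink superposition, or a numerical
  axisymmetric Stokes stream-function solve), with wall capture and outlet
  counting — including eccentric outlets and flow-rate sweeps.
* **Signal analysis.** The particle-counter chain: detector trace →
  zero-phase 100 Hz low-pass → peak detection → 1-s event counts →
  pile-up-corrected, normalized throughput curve → `t_1/2`; plus a
  synthetic-trace generator (inhomogeneous Poisson arrivals over Gaussian
  noise) with known ground truth for end-to-end validation.

## Worked example: how long do stromal cells last in a 1 ml syringe?

Human bone-marrow stromal cells (literature values: radius 10.3 µm,
density 1.062 g/cm³) suspended in PBS in a 1 ml syringe (barrel radius
2.3 mm):

```r
library(syrsed)
cells <- particle_spec(radius = 10.3e-6, density = 1062)
syr   <- syringe_spec(barrel_radius = 2.3e-3, barrel_length = 40e-3,
                      outlet_radius = 0.5e-3, outlet_length = 5e-3)

terminal_velocity(cells, buffer_pbs())
#> [1] -1.433912e-05

half_life_bounds(cells, buffer_pbs(), syr)
#> <half_life_estimate> bounds = [64.7974, 129.595] s

half_life_estimate(cells, buffer_pbs(), syr, K_S = 0.4)
#> [1] 64.16012
```

The cells settle at 14 µm/s, and at low pump rates half the sample is
already undeliverable after roughly a minute — matching bench experience
that stromal-cell suspensions need remixing within minutes. Simulating
5 µm polystyrene beads in water at 10 µl/min in the 2.2 mm test barrel:

```r
ps5 <- particle_spec(5e-6, 1070)
hl <- simulate_half_life(ps5, buffer_water(),
                         syringe_spec(2.2e-3, 40e-3, 0.5e-3, 5e-3),
                         ul_min(10), sim_config(2000, 0.05, 600, seed = 1))
#> sim t_half = 213 s, K_S = 0.43
```

`K_S = 0.43` sits just above the no-lift bound, as expected at a moderate
flow-rate; raising the flow-rate moves it toward the lens bound and
prolongs the half-life. The practical levers, in order of impact: match
the buffer density, raise the viscosity (within shear-stress limits), use
the largest syringe radius the pump meters reliably, pump as fast as the
setup tolerates, and prefer bottom-eccentric outlets (the simulator shows
them nearly doubling `t_1/2` versus concentric ones at 3.6 mm radius).

A command-line wrapper is installed at `inst/exec/syrsed`
(`estimate | simulate | analyze | synth | sweep`) over YAML configs with
explicit unit suffixes; examples live in `inst/extdata/`.

## Package layout

* `R/specs.R`, `R/core_model.R` — domain types, terminal velocity,
  boundary curves, half-life bounds and `K_S` fitting
* `R/flow_field.R`, `R/stokes_axisym.R` — flow backends
* `R/particle_sim.R` — seeding, advection, capture/exit bookkeeping,
  concentration-curve estimators
* `R/signal_analysis.R`, `R/synthetic_data.R` — measurement chain and
  ground-truth generator
* `R/io.R`, `R/cli.R` — YAML configs (explicit unit suffixes, SI
  internally), tabular curve/trace formats with provenance headers, CLI
* `vignettes/sedimentation-model.Rmd` — the model, its assumptions,
  estimator design and limitations
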