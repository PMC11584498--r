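---
title: "Methods: multiscale modelling of NO-mediated vascular tone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale modelling of NO-mediated vascular tone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `vasotone`, its numerical
treatment, and the design decisions taken where the formulation was
genuinely open. It is the reference for *why* the code looks the way it
does; the README shows *how* to run it.

## The model in one paragraph

A three-segment lumped (0D) arterial network — upstream artery, segment of
interest, downstream vasculature — is driven by a pulsatile half-cosine
inflow with constant stroke volume. The resistance and compliance of the
segment of interest are not prescribed: they derive from a finite-element
(FE) model of its cross section through a sigmoid pressure–area surrogate
`A(p) = a/(1 + exp(-b(p/c - 1))) + d`. The cross-section wall is a
two-layer fiber-reinforced hyperelastic composite whose smooth muscle cells
(SMCs) contract or relax according to the local nitric-oxide (NO)
concentration; NO and reactive oxygen species (ROS) obey a
reaction–diffusion system whose endothelial boundary values respond to the
time-averaged wall shear stress (TAWSS) computed by the 0D model. The two
scales are reconciled at each slow-time step by an Aitken–Steffensen
fixed-point iteration on the TAWSS.

## Tissue mechanics

* **Kinematics.** Generalized plane strain: deformation lives in the
  radial–circumferential plane with a fixed axial pre-stretch
  `lambda_z = 1.3` and no axial shear. Quasi-incompressibility is enforced
  by a perturbed Lagrangian with bulk modulus `kappa = 100 MPa`; the
  element-constant multiplier satisfies `p = kappa (J - 1)` and is
  condensed element-wise (classical Q1/P0 mean dilatation), so the global
  system carries displacement unknowns only.
* **Extracellular matrix.** Isochoric neo-Hookean elastin
  (`mu = 10 kPa`) plus two exponential collagen families at ±45° from the
  circumferential direction (`k1 = 10 kPa`, `k2 = 2.5`), active in tension
  only (Macaulay bracket).
* **Smooth muscle.** Active-strain formulation: the circumferential active
  stretch `lambda_a` enters through a volume-preserving multiplicative
  split, and the first Piola–Kirchhoff fiber stress is the bounded sigmoid
  `P = P_max (2 s(x) - 1)`, `x = (2 C_smc / P_max)(lambda_e - 1)`, with
  stiffness `C_smc = 100 kPa` equal to the tangent at the isometric state
  and `P_max = 100 kPa` the isometric stress bound.
* **Collagen straightening.** A fraction `xi_c = 0.15` of the SMC
  inelastic stretch is transferred to the collagen reference state,
  `lambda_cs = 1 + xi_c (lambda_a - 1)`. **Design decision:** the
  straightening acts on the *squared* fiber invariant,
  `I4e = I4 / lambda_cs^4`, i.e. the inelastic map rescales the fiber
  metric rather than the fiber stretch. With the stretch-level map
  (`I4e = I4 / lambda_cs^2`) the two documented calibration anchors of the
  parameter set — a ≈30% internal-radius reduction from the relaxed
  (`lambda_a = 1.3`) to the basal (`lambda_a = 0.75`) state at 120 mmHg,
  and a basal TAWSS of ≈1.74 Pa — are both missed by roughly a factor of
  two in the separation (≈18% and ≈1.35 Pa); the metric-level map
  reproduces both (the acceptance suite measures ≈28% and ≈1.73 Pa). Both
  maps are identical at `xi_c = 0` and at `lambda_a = 1`.
* **Calcification.** An angular sector of the media (default one third of
  the circumference, full media depth, centred at θ = 0) is replaced by a
  3-term quasi-incompressible Yeoh solid (`c1 = 302`, `c2 = -228`,
  `c3 = 261` kPa) with no muscle, no fibers and no species transport.
* **Loads and constraints.** The lumen pressure is a follower load on the
  deformed intima. Because the boundary is closed, the load is conservative
  with potential `-p lambda_z A_lumen`; the `lambda_z` factor converts the
  current axial length back to the unit reference length used by the energy
  integral. Rigid-body modes are removed by three *tangential* point
  constraints (outer boundary nodes at θ = 0, π/2, π). Pinning a node fully
  — a common alternative — would suppress its radial motion and stress an
  inflating annulus spuriously, so it was rejected.

## Nonlinear solver

Bilinear quadrilaterals with 2×2 Gauss quadrature; the element tangent is a
central finite difference of the analytic element residual (step 1e-6 mm),
verified against a global differencing of the residual to ~1e-9 relative
accuracy. The Newton driver has three layers:

1. a fast nonmonotone pass (full steps, halved only on element inversion)
   — the volumetric penalty often makes the residual grow transiently
   before quadratic convergence sets in, so monotone line searches are
   counterproductive here;
2. a monotone trust-region pass (cap on the max nodal increment, adaptive
   between 0.01 and 1 mm) for states with indefinite or nearly singular
   tangents — the stiff calcified arc under the in-plane compression
   induced by the axial pre-stretch has a nearly neutral bending mode;
3. outer continuation: pressure-step halving, and as a last resort an
   activation ramp (`lambda_a` scaled in ten increments) from the
   *isochoric cold start* `u = (lambda_z^{-1/2} - 1) X`, which satisfies
   `J = 1` exactly and avoids the large spurious volumetric shock of a
   zero-displacement guess under axial pre-stretch.

Convergence: relative residual 1e-8 (absolute floor 1e-8 kPa·mm, matching
the finite-difference tangent accuracy).

## Chemo-biology

Material concentrations on the reference mesh with the pulled-back metric
`J C^{-1}` of the converged mechanical state at the mean pressure of the
most recent fast-scale solve. Diffusion and mass matrices are
assembled once per committed deformation; the bilinear NO–ROS scavenging
reaction is evaluated nodally and weighted by the *lumped* mass matrix.
Lumping keeps the discrete operator monotone, which matters here: the NO
boundary layer is thinner than an element, and consistent-mass weighting
produces spurious sub-basal undershoots one node row into the wall —
amplified by the steep tone sigmoid, these can even invert the ordering of
dysfunction scenarios. The nodal reaction also makes the uniform basal
state an *exact* steady state: the closure `C_ROS_b = (P_NO_b/C_NO_b - eta_NO)/K_RNS`,
`P_ROS_b = K_RNS C_ROS_b C_NO_b` zeroes the reaction at every node and
uniformity zeroes the diffusion. Time stepping is backward Euler with inner
Newton; steady states are solved directly with pseudo-transient
continuation as fallback.

Two parameter notes:

* **NO decay rate.** The tabulated basal values (production 80 nM/s,
  concentration 10 nM, ROS 1.7475 nM / 69.9 nM/s) are consistent only with
  `eta_NO = 1.01 /s`; the sometimes-quoted "0.01 s" is dimensionally and
  numerically incompatible with the closure and is not used (it remains
  config-overridable).
* **Boundary-layer caveat.** The closure pins the *total* NO consumption
  rate at `P_NO_b / C_NO_b = 8 /s` regardless of how it splits between
  first-order decay and ROS scavenging. The steady NO penetration depth is
  therefore `sqrt(D/8) ≈ 10 µm` — thinner than one element at any
  practical resolution. Non-basal NO fields are consequently
  boundary-layer fields, and the tone regulation acts through the
  element-scale representation of that layer; this is inherent to the
  parameter set, not to this implementation. The solver itself is verified
  against a dense radial oracle on a diffusion-resolved variant of the
  problem (diffusivity scaled ×100), where nodal profiles agree to better
  than 1%.

The NO–tone map is the bounded sigmoid through
(`C_NO_b`, `lambda_b = 0.75`) with limits `lambda_minus = 0.59` and
`lambda_plus = 1.3` and slope parameter `k_lambda = 100`. Its offset
constant is `a_lambda = lambda_minus + b_lambda`; with this choice all
three anchor conditions hold exactly (the commonly printed denominator
`2(lambda_plus - lambda_minus)` violates the basal anchor). Per-element
tone uses the average of the four corner NO values.

## Hemodynamics and coupling

* Backward-Euler integration of the three pressure unknowns at 200 steps
  per beat, with the pressure-dependent `R_S(p)`, `C_S(p)` of the segment
  of interest re-evaluated by Picard iteration within each step (the
  dependence is weak over one step; iterated to 1e-11).
* Unknown initial conditions are flushed by fictitious pre-beats
  (`n_pre/f_h ≥ 5 s`); TAWSS and mean pressures are trapezoidal averages
  over the physical 3-beat window.
* Blood viscosity `mu_b = 3.5 mPa·s` (dynamic) and outflow pressure
  `P_out = 0 mmHg` are not part of the published parameter set; these
  defaults give a mean segment pressure near 95 mmHg and a basal TAWSS
  near the tabulated 1.74 Pa with the default geometry.
* **The basal TAWSS is computed, not prescribed**: the basal run (uniform
  `lambda_a = 0.75`, basal heart rate) defines `tau_b`, which then anchors
  the endothelial shear response. This makes basal homeostasis a fixed
  point of the coupled map by construction, to solver tolerance.
* The Steffensen update uses the standard minus sign,
  `tau - (g(tau)-tau)^2 / (g(g(tau)) - 2 g(tau) + tau)` (verified by
  one-step exactness on affine maps, which the plus-sign variant fails),
  with the absolute value of the NO-concentration error as the stopping
  criterion (`tol = 1e-3`) and midpoint re-initialization when the error
  grows. g-evaluations are memoized within an iteration; each committed
  state re-evaluates g at the accepted TAWSS so that the result never
  depends on the number of inner iterations. Equilibrium runs use the
  steady chemistry limit inside g plus an outer loop that refreshes the
  transport metric at the converged mean pressure.

## Scenarios and schedules

Heart-rate ramps follow a piecewise-linear 60 → 120 → 180 bpm profile over
one hour (plateaus reached at 0, 12 and 26 minutes; the 2-minute ramp
durations between the documented plateau times are a package choice and are
config-exposed). Slow steps default to 10 s on ramps and 60 s on plateaus.
Endothelial dysfunction scales the shear-sensitive production term by
`1 - alpha_dys` (0.5 mild, 0.9 severe). The prescribed-TAWSS local
scenarios ramp the shear by ±50% over 2 minutes and bypass the 0D model
and the fixed-point loop entirely.

## What the geometry generator does and does not emulate

The cross-section generator produces a structured polar-product
quadrilateral mesh of a two-layer annulus (media 0.8 mm, adventitia
0.4 mm, internal radius 5.55 mm), optionally perturbed by a seeded
low-order Fourier mode bounded by `eta` times the minimum layer thickness
("quasi-circular"), and optionally carrying the calcified sector. It does
not emulate patient-specific contours, branching, residual stresses or
axial tapering — conclusions drawn from passing tests therefore concern
the idealized segment, not real vascular anatomy. The exact construction
used for the published mesh is not documented anywhere we could follow;
the structured grid with the stated perturbation bound is this package's
reconstruction, and all nominal results use `eta = 0`.

## Problem sizes

Unit tests run on 32–288-element meshes; the acceptance script uses 576
elements for the paired equilibria, 288 for the hour-long heart-rate
schedules (with 10/60 s slow stepping), and 1536 vs 3072 elements for the
mesh-sensitivity study. The production-resolution mesh (about 1500
elements) matches the published discretization; the mesh-sensitivity
numbers justify the scaled-down meshes elsewhere.

## Known limitations

* The calcified arc changes the *effective* (area-derived) lumen radius at
  mean pressure by about −6%, which translates into a TAWSS increase of
  ~+20% with frozen tone — substantially weaker than the published +55%.
  The local radius at the centre of the calcified sector shrinks by ~14%
  (which *would* give ~+57% if the shear were evaluated with it), but the
  shear law prescribes the area-derived radius. Since the inclusion's
  shape is only loosely documented ("approximately one third" of the
  media), the discrepancy is recorded rather than tuned away; all
  calcification-derived percentages inherit it.
* No residual stresses/opening angle, no viscoelasticity, no growth and
  remodelling, no actin–myosin calcium dynamics, single
  chemo-mechanically active segment, 2D cross section only.
* The unloaded (p = 0) state of the calcified section sits near a
  bifurcation (compressed stiff arc); the trust-region solver converges to
  a nearby stable state, but path-dependence at exactly p = 0 cannot be
  excluded on principle. Operating pressures (≥ diastolic) are far from
  this regime.
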