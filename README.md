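# vasotone

Multiscale simulation of nitric-oxide-mediated vascular tone regulation in
R.

Vascular tone — the degree of smooth-muscle contraction in an artery wall —
couples two very different scales. Globally it sets the resistance and
compliance that shape blood pressure and flow over each heartbeat; locally
it responds, over minutes, to the wall shear stress that the flow itself
exerts on the endothelium, through nitric oxide (NO) signalling. `vasotone`
implements a two-way coupled model of this loop for researchers in
computational cardiovascular biomechanics:

* a **0D lumped network** (upstream artery, segment of interest,
  downstream vasculature) integrated by backward Euler over the fast
  (heartbeat) time scale, with a raised-cosine inflow of constant stroke
  volume;
* a **2D finite-element cross section** of the segment of interest:
  two-layer fiber-reinforced hyperelastic wall (neo-Hookean elastin +
  exponential collagen at ±45°), active-strain smooth muscle with a
  bounded sigmoid stress law, mixed Q1/P0 quasi-incompressibility, and the
  lumen pressure as a follower load;
* a **NO–ROS reaction–diffusion system** on the wall with
  shear-stress-dependent Michaelis–Menten endothelial production; the NO
  field sets the SMC active stretch `lambda_a(C_NO)` (a sigmoid through
  the basal point with hard bounds 0.59–1.3) and a collagen
  "straightening" stretch slaved to it;
* a **pressure–area surrogate** `A(p) = a/(1+exp(-b(p/c-1))) + d` fitted
  to FE inflation sweeps, which hands `R_S(p) = 8 pi mu ell / A(p)^2` and
  `C_S(p) = ell dA/dp` to the network; and
* an **Aitken–Steffensen fixed-point iteration** on the time-averaged wall
  shear stress (TAWSS) that closes the global–local loop at every slow
  time step.

Supported studies: basal homeostasis, a calcified medial sector (stiff
Yeoh inclusion, no diffusion), endothelial dysfunction (damage factor on
the shear-sensitive NO production), heart-rate ramps (60 → 120 → 180 bpm)
and prescribed-TAWSS local experiments.

## Worked example

```r
library(vasotone)

cfg <- default_config()                      # tabulated parameter set
cfg$mesh <- list(n_circ = 32, n_radial_media = 6,
                 n_radial_adventitia = 3, seed = 1L)

ctx <- build_context(cfg)                    # basal reference + caches
eq  <- solve_coupled_equilibrium(ctx)        # healthy coupled equilibrium
eq$tau
#> [1] 1.734297
ctx$basal$p_mean
#> [1] 94.05188

ctx_c <- build_context(cfg, calcified = TRUE, mesh = ctx$mesh,
                       basal = ctx$basal)
eq_c  <- solve_coupled_equilibrium(ctx_c)
100 * (eq_c$tau / eq$tau - 1)                # TAWSS rise due to calcification
#> [1] 5.028624
```

The first number is the model's own basal TAWSS (Pa): the wall shear
stress of the healthy segment at 60 bpm, computed — not prescribed — from
the coupled equilibrium, and close to the literature value of 1.74 Pa for
this calibration. The second is the mean pressure (mmHg) of the segment
over a heartbeat. The last line quantifies adaptive homeostasis: replacing
a third of the media by a calcified inclusion raises the equilibrium shear
stress, and NO-mediated dilation of the remaining healthy muscle absorbs
part of the insult (freezing the tone at its basal value roughly triples
the rise).

Scenario runs write CSV/VTU/JSON outputs:

```r
res <- run_scenario("heart_rate_ramp", cfg)
write_outputs(res, cfg, dir = "out_ramp")
```

A thin CLI with the same entry points ships in `inst/cli/vasotone`
(`run`, `sweep`, `check`).

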