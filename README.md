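# organoflux

Transport modelling for 3D microfluidic intra-organoid delivery.

Buckled microfluidic cages can embed tapered wing microchannels inside a
living organoid; reagents driven by a few hundred pascals of hydrostatic
head cross a 10 um nanoporous PETE membrane (200 nm pores) into the
tissue, mimicking vascular delivery. `organoflux` is an R package for the
physics of that delivery chain, aimed at microphysiology and
organ-on-chip groups who want desk-scale quantitative estimates of
delivery rates, penetration and timing without a commercial FEA package:

* **Channel hydraulics** — Fourier-series laminar flow in rectangular
  microchannels, lubrication treatment of the tapered wings, Reynolds and
  Peclet diagnostics.
* **Darcy leakage flow** — creeping flow through membrane and tissue
  permeabilities, reduced to spherical symmetry.
* **Porous-media advection–diffusion** — a conservative finite-volume
  solver for the balance
  `eps dc/dt = div(D_eff grad c - u c)` with
  `D_eff = s(t) eps D / tau`, where the membrane saturation follows the
  wetting law `s(t) = min(s0 + ks t, 1)`. Stiff BDF time integration with
  an auditable mass balance.
* **Calibration** — `fit_saturation()`, a bounded Levenberg–Marquardt fit
  of `(s0, ks)` (optionally `D`) against concentration-profile time
  series, returning a classed model object with `coef`, `summary`,
  `vcov`, `predict`, `residuals`, `plot` and `simulate` methods.
* **Synthetic measurements** — seeded generators of fluorescence-like
  line profiles and radial MRI-style intensity profiles, with manifests
  that regenerate bit-identically.

## Worked example

Delivery of 10 uM sulforhodamine B through the saturating membrane into a
5 mm agarose phantom with a sink at the far end:

```r
library(organoflux)
mats <- default_materials()

effective_diffusivity(default_solutes()$magnevist, mats$membrane, s = 1)
#> [1] 42.3

res <- solve_phantom(times = seq(0, 16 * 3600, by = 600))
steady_state_time(res)
#> Steady state (5% L-inf criterion) at t = 1.8e+04 s (5 h)
interface_flux(res)
#> Interface flux (uM.um/s per unit area):
#>   time average 0 -> steady state (5 h): 1.634
#>   steady value: 0.9115
#>   whole-run average: 1.152
```

The first number is the effective diffusivity of the MRI contrast agent
through the fully wetted membrane (porosity 0.094 times free diffusivity
450 um^2/s). The phantom needs about 5 h to settle within 5% of its
steady profile, and the time-averaged solute flux across the nanoporous
interface over that approach is about 1.6 uM.um/s (the steady flux is
lower because the early-time flux into the empty gel is large).

Calibrating the wetting law against a noisy synthetic dataset recovers
the generating parameters (s0 = 0.075, ks = 3.7e-5/s):

```r
synth <- generate_phantom_profiles(noise = c(0.01, 0.005), seed = 42)
fit <- fit_saturation(synth$data)
summary(fit)
#> Membrane saturation fit
#>
#> Coefficients:
#>       Estimate  Std. Error
#> s0 7.55182e-02 1.04919e-03
#> ks 3.64942e-05 4.25141e-07
#>
#> Residual standard error: 0.06629 on 1109 degrees of freedom
```

And the leakage flow into the embedded organoid at the 690 Pa delivery
head:

```r
darcy_radial_flow(spheroid_domain(), mats$organoid, mats$membrane, dp = 690)
#> Darcy leakage flow: dp = 690 Pa -> Q = 8.797e+06 um^3/s
#>   max |u_r| = 4.711 um/s at r = 385.5 um (source shell 385.5 um, surface 993.3 um)
```

The peak velocity is an order-of-magnitude quantity: the spherical
reduction concentrates the whole membrane conductance at one shell (see
the methods vignette, `vignettes/transport-model.Rmd`).

A thin command-line wrapper ships in `inst/exec/organoflux` with
subcommands `hydraulics`, `simulate-phantom`, `simulate-organoid`,
`metrics`, `fit` and `synth`; every stage writes a JSON manifest of its
resolved constants alongside its CSV/JSON outputs.

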