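---
title: "Transport modelling of intra-organoid microfluidic delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport modelling of intra-organoid microfluidic delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoflux)
```

## The physical problem

A buckled 3D microfluidic cage embeds eight tapered wing microchannels
inside a growing tissue spheroid (an organoid of roughly 2 mm diameter).
Each wing is sealed on top by a 10 um nanoporous polyester (PETE) membrane
(200 nm pores, about 3e8 pores/cm^2); a 1 um parylene coating restricts
solute exchange to defined openings. Reagents driven by a small hydrostatic
head (hundreds of pascals) flow along the channels and cross the membrane
into the surrounding tissue or an agarose phantom, by diffusion with a weak
advective component.

`organoflux` models this delivery chain end to end:

1. **Channel hydraulics** — laminar pressure-driven flow in the rectangular
   microchannels (classical Fourier-series duct solution; the tapered wing
   as uniform segments in series).
2. **Darcy leakage** — creeping flow through membrane and tissue treated as
   porous media, reduced to spherical symmetry.
3. **Porous-media advection–diffusion** — the core transient solver for
   solute transport through the time-saturating membrane into layered
   media.
4. **Calibration** — nonlinear least-squares estimation of the membrane
   wetting parameters from concentration-profile time series.

## Governing model and assumptions

Within each porous domain the solute balance is

$$\varepsilon \frac{\partial c}{\partial t}
  = \nabla \cdot \left( D_\mathrm{eff} \nabla c - \mathbf{u}\, c \right),
\qquad
D_\mathrm{eff} = \frac{s\,\varepsilon\, D}{\tau},$$

with porosity $\varepsilon$ entering the storage term, free diffusivity $D$
in water, tortuosity $\tau = 1$ throughout by default, and saturation
$s = 1$ in fully wetted domains. Solute partitioning between adjacent media
is taken as unity. The nanoporous membrane wets gradually after flow
starts; its saturation is linear in time and capped at full saturation,

$$s(t) = \min(s_0 + k_s t,\, 1),$$

with defaults $s_0 = 0.075$ and $k_s = 3.7\times10^{-5}\,\mathrm{s^{-1}}$
(full wetting at $25{,}000$ s, about 6.9 h). The cap is a physical
necessity the bare linear law lacks; `saturation_crossover()` reports the
crossover time.

Flow is inertia-free: the duct Reynolds numbers are of order $10^{-3}$, so
every hydraulic quantity is strictly linear in the applied pressure, and
porous-media flow obeys Darcy's law
$\mathbf{u} = -(k/\eta)\nabla p$ with permeability $k$ per domain.

### Material and solute constants

All defaults live in a YAML table (`inst/extdata/constants.yaml`) resolved
by `of_constants()`; any entry can be overridden per run and the resolved
set is recorded in run manifests. The key values: porosities 0.094
(membrane), 0.2 (organoid), 0.99 (agarose); permeabilities 1.2e-16,
3.75e-15 and 8.2e-16 m^2 respectively; water at 997 kg/m^3 and
1.0016e-3 Pa.s; free diffusivities 450 (Magnevist), 470 (sulforhodamine B)
and 250 (iohexol) um^2/s; source concentrations 5.6 mM, 10 uM and
300 mg/mL (365.3 mM at 821.14 g/mol); pressure presets 690, 510 and
196 Pa. Internally everything is converted to a {um, s, uM, Pa} unit
system so solver matrices avoid 1e-15-scale entries.

## Geometric reduction

Two simulation domains are used.

**Phantom (1D Cartesian).** The membrane occupies $[-10, 0]$ um, the
agarose slab $[0, 5]$ mm; the channel face is held at the source
concentration (continuous perfusion at constant head justifies the
reservoir assumption), the far end is a perfect sink at zero, all other
boundaries closed. The transverse direction (500 um) is not resolved: the
measurement being emulated is a line profile along the diffusion axis, and
with a source spanning the contact face the problem is one-dimensional to
good approximation.

**Organoid (1D spherical).** The oblate spheroid (semi-axes 1.0 and
0.98 mm) is replaced by its volume-equivalent sphere
($r_{eq} \approx 993$ um), and the wing network by a spherical source
shell at $r_s = 385.5$ um — half the 771 um maximum cage diameter. The
shell is held at the channel concentration; the centre is regular (zero
flux) and the outer surface sees the stirred culture well (sink). This is
deliberately the coarsest model that can be compared to a radial line
profile; it preserves the source-to-surface distances and the qualitative
interior-maximum behaviour, but not the azimuthal structure of eight
discrete wings. Quantities that depend on the true wetted membrane area
(notably the peak Darcy velocity) are therefore order-of-magnitude
results, and are documented as such. The exposed membrane area defaults
to the full shell $4\pi r_s^2$ and is overridable
(`darcy_radial_flow(exposed_area_um2 = )`) because the true exposed area
per wing is not a printed quantity.

The channel taper (inner width 20 to 200 um over 11.7 mm) is interpolated
linearly — the minimal assumption for a taper described only as gradual —
and the cage diameter is piecewise-linear through its measured anchors
(771 um at z = 398 um, 339 um at z = 1.48 mm, 1580 um at z = 2.13 mm),
with the 110 um central bonding region as the base anchor.

## Numerical method

The solver is a conservative cell-centred finite-volume discretisation.

* **Interface diffusivities** are distance-weighted harmonic means, which
  gives exact flux continuity across material boundaries (membrane to
  agarose is a 10-fold diffusivity jump).
* **Advection** uses first-order upwinding. Cell Peclet numbers in every
  configuration of interest are far below 1, so the scheme's numerical
  diffusion is negligible; a guard warns if $Pe_{cell} > 2$.
* **Time integration** is stiff BDF (`deSolve::lsode`) with adaptive step
  control; thin membrane cells make the semi-discrete system stiff. The
  membrane diffusivity is evaluated continuously in time inside the RHS
  rather than lagged per step, which is both simpler and more accurate.
* **Mass auditing.** Cumulative boundary, interface and source-shell
  fluxes are integrated as extra ODE states, so the porosity-weighted
  mass balance can be checked at every output step against the same
  integration accuracy as the concentrations; tracked solves close the
  balance to well below 1e-8 of the delivered mass. Flux tracking couples
  distant states, so it can be disabled (`track_fluxes = FALSE`) to keep
  a banded Jacobian — the calibration loop does this for speed.
* **Grids.** The membrane is resolved by at least 5 cells; the agarose
  grid grows geometrically (factor 1.2) from the membrane cell size to a
  50 um cap. Default phantom grids have ~120 cells, organoid grids ~100
  shells — sizes at which the verification benchmarks (half-space erfc
  solution within 1% RMS, steady slab within 0.5%, observed spatial order
  about 2) all pass while a full 16 h phantom transient solves in about a
  second.
* **Tolerances.** Default `rtol = 1e-9` with absolute tolerance scaled to
  the source concentration; the implicit path is cross-checked against an
  independent explicit RK4 integration of the same spatial operator to
  1e-6 relative in the test suite.

### Steady state and interface flux

"Steady state" is not a self-defining notion for a saturating membrane, so
the criterion is explicit: the earliest output time from which the profile
stays within a 5% relative L-infinity distance of the converged
long-horizon profile. The 5% default is exposed (`rel_tol`) — note that
below ~2% the answer is dominated by the membrane's own wetting time
(6.9 h) rather than by diffusion through the slab.

The interface flux $J = -D_\mathrm{eff}\,\partial c/\partial n$ is
evaluated on the tissue side of the membrane. Because a single reported
average flux rarely states its averaging convention, `interface_flux()`
returns three: the time average from start to steady state (computed
exactly from the integrated cumulative flux, which matters because the
early-time flux decays like $t^{-1/2}$ and a sampled trapezoid
underestimates it), the steady value, and the whole-run average.

## Calibration

`fit_saturation()` estimates $(s_0, k_s)$ — optionally also $D$ — by
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) with the
phantom solve as forward model. Design points:

* Parameters are rescaled to order one ($k_s$ by $10^{-4}$) for
  conditioning.
* The finite-difference Jacobian step (`epsfcn = 1e-6`, i.e. about 0.1%
  relative steps) is chosen to sit well above the forward solver's
  integration noise; with machine-epsilon steps the Jacobian is noise and
  the optimizer stalls at its starting point.
* The loss is unweighted least squares unless the caller supplies its own
  weighting by pre-scaling; residuals are observed minus simulated at each
  observed (time, position), with linear interpolation onto the solver
  grid.
* Standard errors come from the residual Jacobian
  ($\sigma^2 (J^\top J)^{-1}$); a near-singular Jacobian is reported as a
  non-identifiability diagnostic rather than an error.
* Optional multistart draws seeded starting points inside the physically
  plausible regime ($s_0 \le 0.5$, $k_s \le 10^{-4}$). Outside that
  regime — saturation completing before the first observation — the
  residual surface is flat in both parameters and any local optimizer
  stalls; the restriction is a property of the experiment's information
  content, not of the optimizer.
* Identifiability needs observations spanning the transient: at least two
  post-start times, enforced.

The calibration forward model runs on the same default grid as the
synthetic generator; coarser grids (`dx_max = 100`) change recovered
parameters by well under 1% and can be used when fitting many datasets.

## What the synthetic data do and do not emulate

`generate_phantom_profiles()` emulates fluorescence line profiles: 11
times (0–400 min every 40 min) at positions every 50 um along the 5 mm
phantom. `generate_radial_mri_profile()` emulates a normalized radial
intensity profile after 1 h of contrast delivery, through a monotone
(affine) intensity mapping. The noise model is multiplicative 1% plus
additive 0.5% of the peak signal — a fluorescence-like heteroscedastic
choice made once; real measurements were not available to estimate it.
One integer seed governs all draws and every dataset carries a manifest
from which it regenerates bit-identically.

What passing the recovery tests shows is that the *estimator* is correct
and well-conditioned under this noise structure at these sampling
densities. It does not show robustness to what real images add:
photobleaching drift, spatially correlated background, optical blurring
near the membrane, registration error of the line profile, or a
non-affine intensity response. A fit to real data should treat the
reported standard errors as lower bounds.

## Known limitations

* The 3D wing geometry is never reconstructed; radial symmetry makes peak
  advection velocities order-of-magnitude quantities (the spherical model
  concentrates the full membrane conductance at one shell).
* The 2D phantom footprint (wing placement inside the 5 mm by 500 um box)
  is reduced to 1D; the source-segment placement would matter for a 2D
  comparison and is left as configuration.
* No cellular uptake, reaction or oxygen transport; no temperature or
  concentration dependence of viscosity and diffusivity; no elastic
  deformation of channels under pressure.
* Organoid and agarose domains are treated as fully saturated from the
  start; only the membrane carries the wetting law. The conventions
  behind single-number Reynolds and Peclet diagnostics (characteristic
  length and velocity) are configurable because they are rarely stated;
  defaults use the widest cross-section and the membrane thickness
  respectively.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh install: the saturated
membrane effective diffusivity for the contrast agent, the phantom
steady-state time at the 5% criterion, the interface flux under all three
averaging conventions, and the peak radial Darcy velocity at 690 Pa. The
problem sizes are the package defaults described above (about 120 phantom
cells, 16 h horizon at 10 min outputs for the steady-state search).
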