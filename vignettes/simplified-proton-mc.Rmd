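---
title: "A simplified Monte Carlo model of a double-scattering proton beamline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simplified Monte Carlo model of a double-scattering proton beamline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protonmc)
```

## The problem and the modelling idea

Passive (double-scattering) proton delivery produces a spread-out Bragg peak
(SOBP) by sweeping a rotating range-modulator wheel through the beam while
two scatterers flatten the field. A faithful Monte Carlo model of such a
treatment head is a months-long engineering effort and most of its computing
time is spent inside the nozzle, not in the patient. `protonmc` takes the
opposite route: the nozzle is a hollow absorbing cylinder containing one
lead foil, and everything the hardware does to the beam is encoded in a
*time-independent source*: discrete energy layers with weights and Gaussian
energy spreads, sampled from a disk with a fixed angular spread. Relative
dose in the phantom is then a standard condensed-history transport problem.

This vignette records the model, its numerical choices, and what the test
suite does and does not establish.

## Range-energy model and materials

Proton range in water follows the Bragg-Kleeman power law
$R = \alpha E^p$ with $\alpha = 0.0022\,$cm/MeV$^p$, $p = 1.77$ — literature
constants that reproduce clinical ranges to a few percent over 1–250 MeV
(102.7 MeV → 8.0 cm, 147.6 MeV → 15.2 cm). Stopping power is its exact
derivative inverse, $S(E) = 1/(\alpha p E^{p-1})$, capped below 0.25 MeV
where the CSDA expression diverges (the residual is deposited locally).
This is an explicit stand-in for full physics tables: simple, invertible,
and consistent between the transport engine and the analytic oracle by
construction.

Non-water materials carry only a mass density, a relative stopping power
(RSP) and a radiation length. Energy loss is tracked in water-equivalent
thickness (WET = thickness × RSP); scattering uses the material's own
radiation length. There are no per-material range tables — that matches how
the source itself is derived (everything in WET) and keeps heterogeneity
handling transparent. The bundled bone (RSP 1.6) and lung (RSP 0.26)
surrogates are generic, not a CT calibration; tests assert only qualitative
behaviour behind them (range pulled back behind bone, pushed forward behind
lung).

## The source model

For a prescription (range $R$, modulation $M$, both cm of water):

* **Layers.** The deepest layer satisfies
  $\alpha E^p = R + \mathrm{WET}({\rm foil})$; successive layers are pulled
  back in WET until the pullbacks span $[0, M]$. The foil WET is compensated
  up front so the in-water range is the prescribed one, which also makes the
  pristine-peak depth invariant to the foil thickness (verified to < 1 mm).
* **Spreads.** Each layer's energy sigma is the quadrature sum of the
  entrance spread of the cyclotron beam and the range straggling the real
  (un-modelled) nozzle hardware would have added. Defaults:
  $\sigma_{\rm in} = 0.007E$ and $\sigma_R = 0.012\,R^{0.935}$ cm converted
  to MeV via $S(E)$. Both are injectable functions — they stand in for
  published parameterisations that are cited, not reproduced, in the
  commissioning literature.
* **Weights.** With no vendor data available, weights come from non-negative
  least squares (Lawson–Hanson) against the analytic oracle: minimise the
  squared deviation of the synthesised SOBP from a flat plateau. The problem
  is convex and the solver deterministic. A `machine_config` (per-step WETs,
  dwell angles, start angle, current modulation) bypasses the optimiser;
  `adjust_first_layer()` reproduces the start-angle trim used at
  commissioning.

### Layer spacing is adaptive, not fixed

A pullback step much wider than the pristine peak's Gaussian width aliases
into plateau ripple *no weight choice can remove* (the basis functions
simply cannot interpolate between the peaks). With the default spread
model the peak width at range 8 cm is ≈ 0.17 cm, so a fixed 0.5 cm step
would leave ±10% ripple. `source_model()` therefore spaces layers at 1.1×
the deepest layer's Gaussian range spread (capped at 0.5 cm, floored at
0.15 cm). `build_energy_layers()` still takes any explicit spacing.

### Commissioning against the oracle

Real systems are commissioned against measurements; here the analytic
oracle plays that role, deterministically and before any MC run:

* the deepest layer is adjusted so the *pristine distal 90%* depth equals
  $R$ (the clinical range definition, not the bare CSDA range);
* the pullback span is adjusted so the SOBP's *proximal-to-distal 90%*
  distance equals $M$. At large $M/R$ the 90→100% proximal ramp of any
  physical SOBP is ~1 cm wide, so a source whose flat top spans exactly
  $[R-M, R]$ would overshoot the 90%-to-90% modulation by ~1 cm; the vendor
  convention (modulation measured 90% to 90%) is taken as authoritative;
* layer energies receive a small obliquity allowance
  $\Delta R = R\,\langle\theta^2\rangle/2$ with
  $\langle\theta^2\rangle = 2\sigma_{\rm foil}^2 + \langle\theta_c^2\rangle$:
  protons leave the foil at an angle, so their stopping *depth* projects
  slightly short of their range (~0.2 mm for a 2 mm foil at range 8). The
  oracle never sees this allowance (`effective_layers()` removes it), so
  oracle-vs-MC comparisons remain a genuine cross-check.

## Beamline

Devices are thin-plane operators — an energy/angle kick at a plane — not
volumetric geometry. The foil scatters with the Highland sigma for lead and
degrades by its WET; the nozzle wall is a perfect absorber at the exit
plane (radius 13 cm); the aperture is a perfect absorber with an inclusive
boundary; the compensator looks its thickness up nearest-pixel (sharp
edges, per the stair-compensator benchmark) and ignores lateral transport
inside the slab. The snout distance is not documented for the modelled
system; the aperture sits 40 cm and the compensator 38 cm upstream of
isocenter by default, both configurable. Air gaps are treated as vacuum.

One consequence worth knowing: the *apparent source size* is dominated by
foil scatter (the thicker the foil, the larger the apparent source), so
lateral penumbras are generous with the default 2 mm foil. The
penumbra-growth-with-depth property is therefore demonstrated with a
0.75 mm foil, the thin end of the commissioned span, where in-water
scattering is not swamped by the source term.

## Transport

A class-II-style condensed-history loop, vectorised over all live protons:

* step = min(1 mm, 0.2 × residual physical range, distance to the next
  phantom-voxel boundary) — no step crosses a material interface;
* continuous energy loss from the range model plus Gaussian straggling with
  Bohr variance 0.087 MeV²/cm WET (clamped to $[0, E]$); deposits are binned
  at the step midpoint on a scoring mesh that may differ from the phantom
  grid;
* Highland deflection with the local material's radiation length;
* nuclear removal with probability $1 - e^{-\Lambda\,\mathrm{step}_{\rm WET}}$,
  $\Lambda = 0.012$/cm; a removed proton deposits 60% of its remaining
  energy locally, the rest is booked as escaped — declared stand-ins for
  hadronic physics, and applied identically (analytically) in the oracle;
* cutoff 0.5 MeV, deposit-on-kill; energy bookkeeping closes exactly
  (launched = deposited + escaped), which the suite asserts to 10⁻⁶.

Statistical uncertainty uses batch statistics: histories are split into
contiguous batches (default 10), per-voxel sums and squared sums of batch
deposits give the relative SEM; the region value averages voxels above 50%
of the maximum. With one history per batch this reduces to the textbook
per-history estimator (the `{1, 1, 2}` hand example in the tests). The
estimator itself carries ~10% noise at 10 batches, which is why the
1/√N-scaling test averages over repeated runs.

## The analytic oracle

`pristine_bragg()` is deliberately independent of the transport code (they
share only the materials module): CSDA dose with the same nuclear fluence
factor, convolved with a Gaussian range spread combining the beam's energy
sigma and the straggling the phantom itself accumulates
($\sigma^2 = k_B \int S^{-2} dz$, same $k_B$). Two numerical points:

* each cell of the convolution grid holds the *exact energy loss across the
  cell divided by its width*, not a point sample — the end-of-range
  stopping-power singularity is integrable, and point-sampling it gives the
  curve a grid-offset-dependent mass error of several percent, which would
  silently corrupt the weight optimisation;
* the oracle has no surface buildup model (its entrance is a flat
  extension), so point-wise MC comparisons start at 2 mm depth; gamma and
  r90 comparisons are unrestricted.

## Metric conventions

Range ≔ distal r90; modulation ≔ distal r90 − proximal r90; falloff ≔
distal r80→r20; all crossings linearly interpolated, scanning from the deep
end so noise in the plateau cannot alias the distal values. Flatness is
half the peak-to-peak excursion over the plateau, where the plateau starts
at the *proximal 98% crossing* plus a 0.5 cm margin — starting at p90 would
pull the physical 90→100% proximal ramp into the window at high $M/R$ and
declare every real SOBP "unflat". Depth-dose normalisation sets the plateau
mean (pristine: peak) to 100. The "2% or 2 mm" comparison is
operationalised as the standard global-normalisation gamma index with a 10%
low-dose threshold.

## What the synthetic world does and does not establish

The generator emulates: prescribed range/modulation recovery, SOBP
flatness, foil-thickness effects on apparent source size, sharp lateral
heterogeneity behind a stair compensator, and bone/lung range shifts. It
does not emulate: the true nozzle hardware (scatterer design, wheel
geometry), measured beam data, absolute dose, secondary particles, detector
response, or CT-based patients. A green acceptance suite therefore
establishes *self-consistency* — the transport engine reproduces the
commissioned source's prescription and agrees with an independent analytic
model at gamma(2%/2 mm) ≥ 95% — not agreement with any physical machine's
measurements, which are not publicly available.

## Known limitations

* The Bragg-Kleeman/Highland/Bohr/exponential-attenuation quartet is a
  stand-in physics list; constants are configurable but not fitted to data.
* Thin-plane devices ignore lateral transport inside compensators (edge
  scatter and slit scatter are out of scope).
* Lateral penumbra magnitude is tied to the foil surrogate; with thick
  foils the apparent source (and hence the penumbra) is larger than a real
  contoured-scatterer system would give at the same range.
* The stair-compensator pullback check locates the distal edge at the 80%
  level: behind a thick step the shifted SOBP's hump rides at 85–95% of the
  plateau normalisation and a 90% locator aliases into plateau noise.
* Full-modulation beams ($M = R$) are accepted by the layer builder but the
  foil then absorbs the shallowest layer; commissioning such beams needs a
  thinner foil.
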