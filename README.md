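# protonmc

A self-contained, simplified Monte Carlo dose engine for **double-scattering
proton therapy**, written in R. It is aimed at medical-physics researchers
who want a transparent, desk-scale model of a passive-scattering treatment
head: instead of simulating scatterers, range-modulator wheels and ion
chambers, the whole nozzle is reduced to a single lead foil inside an
absorbing cylinder, and all of the real beamline complexity is folded into a
**time-independent source model**.

## The model

A clinical beam is prescribed by its *range* R (depth of the distal 90% dose
level, cm of water) and *modulation* M (proximal-to-distal 90% distance). The
source that delivers it is described by three components:

1. **Discrete energy layers** `E_i`, one per range-modulator step, spaced in
   water-equivalent pullback so that layer ranges span `[R - M, R]` (the lead
   foil's water-equivalent thickness is compensated in the layer energies);
2. **Layer weights** `w_i`, found by non-negative least squares against an
   analytic Bragg-curve oracle so that the summed spread-out Bragg peak
   (SOBP) is flat to within ±2% — the package's stand-in for the vendor's
   modulation spreadsheet (a machine table with per-step dwell angles,
   current modulation and start angle is accepted too);
3. **Per-layer energy spreads** `sigma_i`, the quadrature sum of the
   cyclotron entrance spread (`0.007 E`) and the range straggling the
   un-modelled nozzle hardware would have produced (`sigma_R = 0.012 R^0.935`
   cm, converted to MeV through the stopping power).

Protons are sampled from a 2.7 cm disk 230 cm upstream of isocenter with a
3.44° half-cone, scattered and degraded by the foil, masked by the patient
aperture, pulled back by the Lucite compensator, and transported through a
voxelised phantom with a condensed-history loop: Bragg-Kleeman
continuous slowing down (`R = alpha E^p`, `alpha = 0.0022`, `p = 1.77`),
Gaussian energy-loss straggling (Bohr variance 0.087 MeV²/cm), Highland
multiple Coulomb scattering
(`sigma = 14.1 MeV/pv * sqrt(x/X0) (1 + log10(x/X0)/9)`), and exponential
nuclear attenuation (rate 0.012/cm, 60% of a removed proton's energy
deposited locally). The analysis surface is the clinical one: depth-dose and
lateral profiles, distal 80–20 falloff, lateral 80–20 penumbra, SOBP range /
modulation / flatness, and gamma-index (2%/2 mm) comparison.

## Worked example

```r
library(protonmc)

set.seed(1)
src  <- source_model(8, 5)            # range 8 cm, modulation 5 cm
st   <- sample_source(src, 2e5)       # protons on the source disk
st   <- beamline_transport(st, src)   # foil, nozzle wall, drift to phantom
tank <- make_water_tank()             # 40 cm cube of water
mesh <- dose_grid(c(-20, -20, 0), c(0.5, 0.5, 0.1), c(80, 80, 120))
dose <- transport_in_phantom(st, tank, mesh)

dd <- depth_dose(dose, box = c(Inf, Inf))   # laterally averaged, plateau = 100
distal_metrics(dd)
#> <pmc_sobp_metrics> r90 7.973 cm | modulation 4.949 cm | distal 80-20 0.253 cm | flatness 0.54%

estimate_uncertainty(dose)$region
#> [1] 0.2692601   # mean per-voxel relative SEM on the 0.5 x 0.5 x 0.1 cm mesh
```

The prescribed range is recovered to 0.3 mm and the modulation to 0.5 mm;
the plateau is flat to ±0.5%. Individual 0.025 cm³ voxels carry ~27%
statistical noise at 2×10⁵ histories, but the laterally averaged curve the
metrics use integrates ~1.7×10⁵ protons per depth bin (sub-percent noise).
The independent analytic oracle agrees with the transport engine at
gamma(2%/2 mm) = 98.8% on this beam:

```r
orc <- sobp_analytic(effective_layers(src), dd$coordinate)
```

A full run (source → devices → phantom → report) is one call driven by a
JSON config, or the CLI:

```sh
Rscript -e 'protonmc::pmc_cli()' simulate --config run.json
Rscript -e 'protonmc::pmc_cli()' build-source --range 15.2 --mod 10 --out src.json
```

## What this is not

No absolute dose or monitor-unit calibration, no secondary-particle
transport, no time-dependent (rotating-wheel) simulation, no CT/DICOM
import, no TPS or detector-array file formats. See the methods vignette
(`vignettes/simplified-proton-mc.Rmd`) for the model's assumptions,
numerical choices and known limitations.
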