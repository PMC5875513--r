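Package: protonmc
Title: Simplified Monte Carlo Dose Engine for Double-Scattering Proton Therapy
Version: 0.1.0
Authors@R:
    person("protonmc", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained, simplified Monte Carlo system for relative dose
    calculation in double-scattering proton therapy. The treatment nozzle is
    reduced to a single lead scattering foil inside an absorbing cylinder, and
    the real beamline complexity is pushed into a time-independent source
    model: discrete energy layers with per-layer weights and energy spreads
    that together reproduce a spread-out Bragg peak (SOBP) of given range and
    modulation. Protons sampled from that source traverse patient-specific
    apertures and Lucite compensators and are transported through voxelised
    phantoms with a condensed-history scheme (continuous slowing down via a
    Bragg-Kleeman range-energy model, Gaussian energy-loss straggling, Highland
    multiple Coulomb scattering, and exponential nuclear attenuation). The
    package ships an independent analytic Bragg-curve oracle used both to
    optimise layer weights and to validate the transport engine, plus the
    standard clinical analysis surface: depth-dose and lateral-profile
    extraction, distal 80-20 falloff, lateral 80-20 penumbra, SOBP range,
    modulation and flatness, and gamma-index comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
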