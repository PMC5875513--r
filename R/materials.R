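#' Material properties
#'
#' A material is described by its mass density, its stopping power relative to
#' water (RSP, per unit length) and its radiation length. Everything the
#' transport engine needs to know about a medium is derived from these three
#' numbers: energy loss is tracked in water-equivalent thickness
#' (WET = thickness x RSP) and multiple Coulomb scattering uses the radiation
#' length through the Highland formula.
#'
#' @param name character label (used as the key in material tables).
#' @param mass_density mass density in g/cm^3; must be > 0.
#' @param relative_stopping_power linear stopping power relative to water
#'   (dimensionless); must be > 0. Water is exactly 1.
#' @param radiation_length radiation length X0 in g/cm^2.
#' @return An object of class `pmc_material`.
#' @examples
#' lucite <- pmc_material("lucite", 1.19, 1.16, 40.55)
#' wet(5.2, lucite)
#' @export
pmc_material <- function(name, mass_density, relative_stopping_power,
                         radiation_length = 36.08) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(mass_density) || mass_density <= 0)
    stop("mass_density must be > 0", call. = FALSE)
  if (!is.finite(relative_stopping_power) || relative_stopping_power <= 0)
    stop("relative_stopping_power must be > 0", call. = FALSE)
  if (!is.finite(radiation_length) || radiation_length <= 0)
    stop("radiation_length must be > 0", call. = FALSE)
  structure(
    list(name = name,
         mass_density = mass_density,
         relative_stopping_power = relative_stopping_power,
         radiation_length = radiation_length),
    class = "pmc_material")
}

#' @export
print.pmc_material <- function(x, ...) {
  cat(sprintf("<pmc_material> %s: rho = %g g/cm^3, RSP = %g, X0 = %g g/cm^2\n",
              x$name, x$mass_density, x$relative_stopping_power,
              x$radiation_length))
  invisible(x)
}

#' Default material table
#'
#' Bundled materials for the phantoms and beamline devices used by the
#' simulator. Lead's "RSP" is a per-cm linear value used only for the foil
#' WET bookkeeping; bone- and lung-like values are generic surrogates, not a
#' calibrated CT conversion. Any entry can be overridden, and new materials
#' added, via `overrides` or [read_material_table()].
#'
#' @param overrides optional named list; each element is either a
#'   `pmc_material` or a list with fields `mass_density`,
#'   `relative_stopping_power` and optionally `radiation_length`.
#' @return Named list of `pmc_material` objects; always contains `water` with
#'   RSP exactly 1.
#' @examples
#' mats <- pmc_materials()
#' names(mats)
#' @export
pmc_materials <- function(overrides = NULL) {
  tab <- list(
    water       = pmc_material("water",       1.000,  1.000, 36.08),
    lucite      = pmc_material("lucite",      1.190,  1.160, 40.55),
    lead        = pmc_material("lead",       11.350,  5.400,  6.37),
    bone        = pmc_material("bone",        1.850,  1.600, 28.00),
    lung        = pmc_material("lung",        0.260,  0.260, 36.08),
    solid_water = pmc_material("solid_water", 1.040,  1.000, 36.08),
    air         = pmc_material("air",         0.0012, 0.001, 36.62)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      if (inherits(ov, "pmc_material")) {
        tab[[nm]] <- ov
      } else {
        base <- if (!is.null(tab[[nm]])) tab[[nm]] else
          list(radiation_length = 36.08)
        tab[[nm]] <- pmc_material(
          nm,
          mass_density = ov$mass_density %||% base$mass_density,
          relative_stopping_power =
            ov$relative_stopping_power %||% base$relative_stopping_power,
          radiation_length = ov$radiation_length %||% base$radiation_length)
      }
    }
  }
  tab
}

#' Load a material table from a JSON config block
#'
#' The file holds an object keyed by material name, each entry with fields
#' `mass_density`, `relative_stopping_power`, `radiation_length`. Entries
#' override or extend the bundled defaults.
#'
#' @param path path to a JSON file.
#' @return Named list of `pmc_material` (see [pmc_materials()]).
#' @export
read_material_table <- function(path) {
  if (!file.exists(path)) stop("material table not found: ", path, call. = FALSE)
  pmc_materials(overrides = jsonlite::read_json(path, simplifyVector = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bragg-Kleeman range-energy model
#'
#' Power-law relation between proton kinetic energy and residual range in
#' water, `R = alpha * E^p`. This is a deliberately simple stand-in for full
#' physics tables; with the default constants it reproduces clinical proton
#' ranges to within a few percent over 1-250 MeV (e.g. 102.7 MeV -> 8.0 cm,
#' 147.6 MeV -> 15.2 cm).
#'
#' @param alpha range constant in cm/MeV^p (water). Default 0.0022.
#' @param p dimensionless exponent. Default 1.77.
#' @param energy_cap_mev stopping power below this kinetic energy is capped at
#'   its value at the cap (the CSDA stopping power diverges as E -> 0; the
#'   residual energy below the cap is deposited locally by the transport
#'   engine). Default 0.25 MeV.
#' @return Object of class `pmc_range_model`.
#' @examples
#' m <- range_energy_model()
#' range_from_energy(102.7, m)
#' energy_from_range(8.0, m)
#' @export
range_energy_model <- function(alpha = 0.0022, p = 1.77, energy_cap_mev = 0.25) {
  stopifnot(alpha > 0, p > 1, energy_cap_mev > 0)
  structure(list(alpha = alpha, p = p, energy_cap_mev = energy_cap_mev),
            class = "pmc_range_model")
}

#' Residual range in water from kinetic energy
#'
#' @param energy_mev proton kinetic energy in MeV (vectorised); must be >= 0.
#' @param model a [range_energy_model()].
#' @return Residual range in cm of water.
#' @export
range_from_energy <- function(energy_mev, model = range_energy_model()) {
  if (any(energy_mev < 0)) stop("energy must be >= 0", call. = FALSE)
  model$alpha * energy_mev^model$p
}

#' Kinetic energy from residual range in water
#'
#' Exact inverse of [range_from_energy()].
#'
#' @param range_cm residual range in cm of water (vectorised); must be >= 0.
#' @inheritParams range_from_energy
#' @return Kinetic energy in MeV.
#' @export
energy_from_range <- function(range_cm, model = range_energy_model()) {
  if (any(range_cm < 0)) stop("range must be >= 0", call. = FALSE)
  (range_cm / model$alpha)^(1 / model$p)
}

#' Linear stopping power
#'
#' Closed form implied by the Bragg-Kleeman relation:
#' `S(E) = 1 / (alpha * p * E^(p-1))` in water, scaled by the material's
#' relative stopping power. Below `model$energy_cap_mev` the value is capped
#' (the singularity at E = 0 is integrable; transport deposits the remainder
#' locally).
#'
#' @param energy_mev kinetic energy in MeV (vectorised); must be > 0.
#' @param material a [pmc_material()]; default water.
#' @inheritParams range_from_energy
#' @return Stopping power in MeV/cm.
#' @export
stopping_power <- function(energy_mev, material = pmc_material("water", 1, 1),
                           model = range_energy_model()) {
  if (any(energy_mev <= 0)) stop("energy must be > 0", call. = FALSE)
  e <- pmax(energy_mev, model$energy_cap_mev)
  material$relative_stopping_power / (model$alpha * model$p * e^(model$p - 1))
}

#' Water-equivalent thickness of a slab
#'
#' WET = physical thickness x relative stopping power.
#'
#' @param thickness_cm physical thickness in cm (vectorised); must be >= 0.
#' @param material a [pmc_material()].
#' @return Water-equivalent thickness in cm.
#' @export
wet <- function(thickness_cm, material) {
  if (any(thickness_cm < 0)) stop("thickness must be >= 0", call. = FALSE)
  thickness_cm * material$relative_stopping_power
}
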