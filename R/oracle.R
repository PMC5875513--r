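#' Analytic beam description for the depth-dose oracle
#'
#' @param mean_energy kinetic energy in MeV at the phantom surface.
#' @param energy_sigma Gaussian energy spread in MeV (>= 0).
#' @param fluence relative fluence (weight) of the beam.
#' @return Object of class `pmc_analytic_beam`.
#' @export
analytic_beam <- function(mean_energy, energy_sigma = 0, fluence = 1) {
  stopifnot(mean_energy > 0, energy_sigma >= 0, fluence >= 0)
  structure(list(mean_energy = mean_energy, energy_sigma = energy_sigma,
                 fluence = fluence),
            class = "pmc_analytic_beam")
}

# CSDA depth-dose of a proton beam in water before range-spread convolution,
# on a uniform grid of cell width dz: the cell value is the exact energy lost
# across the cell divided by dz (so the stopping-power singularity at the end
# of range is integrated, not point-sampled, and the curve's mass is exact),
# attenuated by the exponential nuclear fluence factor, plus the locally
# deposited fraction of removed primaries. Shares only the materials module
# with the transport engine.
.oracle_base_curve <- function(z, dz, r0, model, nuclear) {
  clamp <- function(r) pmin(pmax(r, 0), r0)
  resid_hi <- clamp(r0 - (z - dz / 2))
  resid_lo <- clamp(r0 - (z + dz / 2))
  csda <- (energy_from_range(resid_hi, model) -
             energy_from_range(resid_lo, model)) / dz
  resid_c <- clamp(r0 - z)
  e_c <- energy_from_range(resid_c, model)
  flu <- exp(-nuclear$lambda * pmax(z, 0))
  d <- flu * (csda + nuclear$lambda * nuclear$local_fraction * e_c)
  d[z - dz / 2 >= r0] <- 0
  d
}

# Intrinsic range-spread variance (cm^2) accumulated by Gaussian energy-loss
# straggling with variance rate `bohr_coeff` (MeV^2 per cm water): an energy
# kick dE at depth u shifts the stopping point by dE / S(E(u)).
.intrinsic_range_variance <- function(r0, model, bohr_coeff) {
  if (bohr_coeff <= 0 || r0 <= 0) return(0)
  u <- seq(0, r0 * 0.999, length.out = 400L)
  e <- energy_from_range(r0 - u, model)
  integrand <- 1 / stopping_power(pmax(e, model$energy_cap_mev), model = model)^2
  sum(diff(u) * (integrand[-1] + integrand[-length(u)]) / 2) * bohr_coeff
}

#' Analytic pristine Bragg curve
#'
#' Independent depth-dose oracle: continuous-slowing-down dose in water from
#' the Bragg-Kleeman model, exponentially attenuated primary fluence with
#' local deposition of a fraction of removed-proton energy, convolved with a
#' Gaussian range spread. The range spread combines the beam's energy sigma
#' (converted to range through the surface stopping power) with the intrinsic
#' straggling accumulated in the phantom. Used to optimise SOBP layer weights
#' and as the acceptance reference for the Monte Carlo engine; it shares only
#' the materials module with the transport code.
#'
#' @param beam an [analytic_beam()].
#' @param depths_cm depths (cm of water) at which to evaluate; must lie within
#'   `[0, 1.2 * range]`.
#' @param model a [range_energy_model()].
#' @param nuclear list with `lambda` (per cm water) and `local_fraction`;
#'   must match the transport engine's policy for comparisons to be meaningful.
#' @param bohr_coeff straggling variance rate in MeV^2/cm water (same constant
#'   as the transport default).
#' @return A [curve1d()] of relative dose (arbitrary units) vs depth.
#' @examples
#' b <- analytic_beam(102.7, 0.8)
#' pb <- pristine_bragg(b, seq(0, 9, 0.02))
#' pb$coordinate[which.max(pb$value)] # close to range_from_energy(102.7)
#' @export
pristine_bragg <- function(beam, depths_cm, model = range_energy_model(),
                           nuclear = nuclear_policy(),
                           bohr_coeff = 0.087) {
  stopifnot(inherits(beam, "pmc_analytic_beam"))
  r0 <- range_from_energy(beam$mean_energy, model)
  if (any(depths_cm < 0) || any(depths_cm > 1.2 * r0 + 1e-9))
    stop("depths must lie within [0, 1.2 * range]", call. = FALSE)

  s0 <- stopping_power(beam$mean_energy, model = model)
  sig2 <- (beam$energy_sigma / s0)^2 +
    .intrinsic_range_variance(r0, model, bohr_coeff)
  sigma_z <- sqrt(sig2)

  dz <- 0.02
  zf <- seq(-5 * sigma_z - 2 * dz, r0 + 5 * sigma_z + 2 * dz, by = dz)
  base <- .oracle_base_curve(zf, dz, r0, model, nuclear)
  # upstream of the surface the beam sees no material: hold the entrance value
  base[zf < 0] <- base[which(zf >= 0)[1]]

  if (sigma_z > 1e-6) {
    half <- ceiling(4 * sigma_z / dz)
    kern <- stats::dnorm(seq(-half, half) * dz, sd = sigma_z)
    kern <- kern / sum(kern)
    conv <- stats::convolve(base, rev(kern), type = "open")
    base <- conv[(half + 1):(half + length(zf))]
  }
  vals <- stats::approx(zf, base, xout = depths_cm, rule = 2)$y
  curve1d(depths_cm, beam$fluence * vals, normalize = FALSE)
}

#' Analytic spread-out Bragg peak
#'
#' Weight-linear superposition of [pristine_bragg()] curves, one per energy
#' layer. Layer energies are taken as in-water surface energies; use
#' [effective_layers()] to fold a foil pullback into a source's layers first.
#'
#' @param layers list of [energy_layer()] objects (weights must be set).
#' @inheritParams pristine_bragg
#' @return A [curve1d()] of summed dose vs depth.
#' @export
sobp_analytic <- function(layers, depths_cm, model = range_energy_model(),
                          nuclear = nuclear_policy(), bohr_coeff = 0.087) {
  if (length(layers) < 1L) stop("need at least one layer", call. = FALSE)
  total <- numeric(length(depths_cm))
  for (ly in layers) {
    if (is.na(ly$weight)) stop("layer weights are unset", call. = FALSE)
    if (ly$weight == 0) next
    b <- analytic_beam(ly$mean_energy, ly$energy_sigma, ly$weight)
    # depths beyond a shallow layer's own domain contribute zero dose
    r0 <- range_from_energy(ly$mean_energy, model)
    ok <- depths_cm <= 1.2 * r0
    if (sum(ok) == 1L) {
      zz <- c(depths_cm[ok], depths_cm[ok] + 1e-4)
      total[ok] <- total[ok] +
        pristine_bragg(b, zz, model, nuclear, bohr_coeff)$value[1]
    } else if (any(ok)) {
      total[ok] <- total[ok] +
        pristine_bragg(b, depths_cm[ok], model, nuclear, bohr_coeff)$value
    }
  }
  curve1d(depths_cm, total, normalize = FALSE)
}
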