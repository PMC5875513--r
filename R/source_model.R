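#' Discrete source energy layer
#'
#' One component of the SOBP source: a near-Gaussian energy line with a
#' relative weight. `pullback_wet` records how far (in cm of water-equivalent
#' range) the layer is pulled back from the deepest layer by the range
#' modulator; the deepest layer has pullback 0.
#'
#' @param mean_energy mean kinetic energy in MeV (> 0).
#' @param energy_sigma Gaussian energy spread in MeV (> 0).
#' @param weight relative weight (>= 0); `NA` while still unset.
#' @param pullback_wet pullback in cm water (>= 0).
#' @return Object of class `pmc_energy_layer`.
#' @export
energy_layer <- function(mean_energy, energy_sigma, weight = NA_real_,
                         pullback_wet = 0) {
  stopifnot(mean_energy > 0, energy_sigma > 0, pullback_wet >= 0)
  if (!is.na(weight) && weight < 0) stop("weight must be >= 0", call. = FALSE)
  structure(list(mean_energy = mean_energy, energy_sigma = energy_sigma,
                 weight = weight, pullback_wet = pullback_wet),
            class = "pmc_energy_layer")
}

#' Vendor-style machine description of a range-modulator track
#'
#' Describes one modulator wheel track plus beam-current modulation, the
#' information a vendor spreadsheet would provide: per-step water-equivalent
#' thicknesses, per-step angular lengths, the start angle (which shortens the
#' first step's effective dwell), and per-step current factors.
#'
#' @param entrance_energy proton energy entering the nozzle, MeV.
#' @param fixed_wet_offset WET (cm water) of scatterers, ion chambers, etc.
#' @param modulator_step_wets per-step absolute WET in cm water (first step
#'   thinnest, typically 0), non-decreasing.
#' @param step_angular_lengths per-step angular lengths in degrees, > 0.
#' @param start_angle wheel angle (degrees) at beam-on; must satisfy
#'   `0 <= start_angle < step_angular_lengths[1]`.
#' @param current_modulation per-step beam-current factors, >= 0.
#' @return Object of class `pmc_machine_config`.
#' @export
machine_config <- function(entrance_energy, fixed_wet_offset = 0,
                           modulator_step_wets, step_angular_lengths,
                           start_angle = 0, current_modulation = NULL) {
  ns <- length(modulator_step_wets)
  if (is.null(current_modulation)) current_modulation <- rep(1, ns)
  if (length(step_angular_lengths) != ns || length(current_modulation) != ns)
    stop("all step lists must have equal length", call. = FALSE)
  if (any(step_angular_lengths <= 0))
    stop("angular lengths must be positive", call. = FALSE)
  if (start_angle < 0 || start_angle >= step_angular_lengths[1])
    stop("start_angle must lie in [0, first step's angular length)",
         call. = FALSE)
  if (any(current_modulation < 0))
    stop("current_modulation must be >= 0", call. = FALSE)
  structure(list(entrance_energy = entrance_energy,
                 fixed_wet_offset = fixed_wet_offset,
                 modulator_step_wets = modulator_step_wets,
                 step_angular_lengths = step_angular_lengths,
                 start_angle = start_angle,
                 current_modulation = current_modulation),
            class = "pmc_machine_config")
}

#' Default entrance energy spread
#'
#' Energy sigma of the beam entering the nozzle, modelled as a fixed fraction
#' of the beam energy. A declared stand-in for the published cyclotron beam
#' characterisation; injectable so an exact form can be dropped in.
#'
#' @param energy_mev kinetic energy in MeV.
#' @param coeff fractional spread (default 0.007).
#' @return Sigma in MeV.
#' @export
entrance_sigma_default <- function(energy_mev, coeff = 0.007) coeff * energy_mev

#' Default range-straggling energy spread
#'
#' Range straggling accumulated in the (un-modelled) physical nozzle,
#' `sigma_R = 0.012 * R^0.935` cm of water, converted to an energy sigma via
#' the stopping power at the layer energy. A declared stand-in for the
#' published straggling theory; injectable.
#'
#' @param energy_mev kinetic energy in MeV.
#' @param model a [range_energy_model()].
#' @return Sigma in MeV.
#' @export
range_straggling_sigma_default <- function(energy_mev,
                                           model = range_energy_model()) {
  r <- range_from_energy(energy_mev, model)
  0.012 * r^0.935 * stopping_power(energy_mev, model = model)
}

#' Per-layer energy sigma by quadrature
#'
#' Combines the entrance energy spread and the nozzle range straggling in
#' quadrature: `sqrt(entrance^2 + straggling^2)`.
#'
#' @param layer_energy kinetic energy in MeV (> 0).
#' @param entrance_sigma_fn function(E) -> MeV; default
#'   [entrance_sigma_default()].
#' @param straggling_fn function(E) -> MeV; default
#'   [range_straggling_sigma_default()].
#' @return Sigma in MeV.
#' @export
compute_layer_sigma <- function(layer_energy,
                                entrance_sigma_fn = entrance_sigma_default,
                                straggling_fn = range_straggling_sigma_default) {
  stopifnot(all(layer_energy > 0))
  se <- entrance_sigma_fn(layer_energy)
  ss <- straggling_fn(layer_energy)
  if (any(se < 0) || any(ss < 0))
    stop("sigma components must be >= 0", call. = FALSE)
  sqrt(se^2 + ss^2)
}

#' Build the discrete energy layers for a beam
#'
#' The deepest layer's energy satisfies
#' `range_from_energy(E) = nominal_range + foil_wet_cm` (the lead foil's WET
#' is compensated up front so the in-water range is the nominal one).
#' Successive layers are pulled back by `layer_spacing` cm of
#' water-equivalent range - or by the modulator step WETs when a
#' [machine_config()] is given - until the pullbacks span
#' `[0, nominal_modulation]`. Weights are left unset; energy sigmas are
#' filled from [compute_layer_sigma()].
#'
#' @param nominal_range prescribed range in cm water (distal reference).
#' @param nominal_modulation prescribed modulation width in cm water;
#'   `0 <= modulation <= range`.
#' @param layer_spacing pullback increment in cm water (default 0.5).
#' @param foil_wet_cm WET of the lead foil in cm water (default 0).
#' @param machine optional [machine_config()]; its step WETs replace the
#'   uniform spacing.
#' @param model a [range_energy_model()].
#' @param entrance_sigma_fn,straggling_fn see [compute_layer_sigma()].
#' @return List of [energy_layer()] ordered by strictly decreasing energy.
#' @examples
#' ls <- build_energy_layers(8, 5, 0.5)
#' length(ls)            # 11 layers, pullbacks 0, 0.5, ..., 5.0
#' ls[[1]]$mean_energy   # about 102.7 MeV
#' @export
build_energy_layers <- function(nominal_range, nominal_modulation,
                                layer_spacing = 0.5, foil_wet_cm = 0,
                                machine = NULL,
                                model = range_energy_model(),
                                entrance_sigma_fn = entrance_sigma_default,
                                straggling_fn = range_straggling_sigma_default) {
  if (nominal_modulation < 0 || nominal_modulation > nominal_range)
    stop("need 0 <= modulation <= range", call. = FALSE)
  if (layer_spacing <= 0) stop("layer_spacing must be > 0", call. = FALSE)
  if (nominal_modulation > 0 && layer_spacing > nominal_modulation)
    stop("layer_spacing exceeds the modulation width", call. = FALSE)

  if (is.null(machine)) {
    pullbacks <- seq(0, nominal_modulation, by = layer_spacing)
    if (utils::tail(pullbacks, 1) < nominal_modulation - 1e-9)
      pullbacks <- c(pullbacks, nominal_modulation)
  } else {
    pullbacks <- machine$modulator_step_wets - machine$modulator_step_wets[1]
  }
  lapply(pullbacks, function(pb) {
    e <- energy_from_range(nominal_range + foil_wet_cm - pb, model)
    energy_layer(e,
                 compute_layer_sigma(e, entrance_sigma_fn, straggling_fn),
                 weight = NA_real_, pullback_wet = pb)
  })
}

#' Layer weights from machine current-modulation data
#'
#' `weight_i` is proportional to `current_modulation_i` times the step's
#' effective angular length; the start angle shortens the first step.
#' Weights are normalised to sum to 1.
#'
#' @param machine a [machine_config()].
#' @return Numeric weight vector.
#' @export
weights_from_modulation <- function(machine) {
  stopifnot(inherits(machine, "pmc_machine_config"))
  len <- machine$step_angular_lengths
  len[1] <- len[1] - machine$start_angle
  w <- machine$current_modulation * len
  if (sum(w) <= 0) stop("all layer weights are zero", call. = FALSE)
  w / sum(w)
}

# Lawson-Hanson non-negative least squares: argmin |A x - b|^2, x >= 0.
# Deterministic active-set method; problems here are tiny (tens of columns).
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * nrow(A)
  x <- numeric(n)
  passive <- logical(n)
  wvec <- as.numeric(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & wvec > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, wvec))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    x <- s
    wvec <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

#' Optimise layer weights against the analytic SOBP oracle
#'
#' Replaces the vendor spreadsheet: finds non-negative weights minimising the
#' squared deviation of the analytic SOBP from a flat plateau over
#' `[range - modulation, range - margin]`. A convex non-negative least-squares
#' problem solved with a Lawson-Hanson active-set method; deterministic.
#'
#' @param layers list of [energy_layer()] with in-water energies (foil WET
#'   already removed; see [effective_layers()]).
#' @param model a [range_energy_model()].
#' @param nuclear a [nuclear_policy()] (oracle fluence factor).
#' @param plateau_margin end margin in cm for the fitted plateau (default 0.1).
#' @param flatness_target maximum acceptable half peak-to-peak plateau ripple,
#'   percent (default 2); exceeding it raises an error identifying the
#'   achieved ripple.
#' @return Numeric weight vector summing to 1.
#' @export
optimize_weights <- function(layers, model = range_energy_model(),
                             nuclear = nuclear_policy(),
                             plateau_margin = 0.1, flatness_target = 2) {
  nl <- length(layers)
  if (nl < 1L) stop("need at least one layer", call. = FALSE)
  if (nl == 1L) return(1)
  ranges <- vapply(layers, function(l) range_from_energy(l$mean_energy, model),
                   numeric(1))
  rmax <- max(ranges); rmin <- min(ranges)
  zs <- seq(max(rmin, 0.05), rmax - plateau_margin, by = 0.05)
  basis <- vapply(layers, function(l) {
    unit <- energy_layer(l$mean_energy, l$energy_sigma, weight = 1,
                         pullback_wet = l$pullback_wet)
    sobp_analytic(list(unit), zs, model, nuclear)$value
  }, numeric(length(zs)))
  target <- rep(mean(basis %*% rep(1 / nl, nl)), length(zs))

  w <- .nnls(basis, target)
  if (sum(w) <= 0)
    stop("weight optimisation collapsed to zero weights", call. = FALSE)
  w <- w / sum(w)

  # judge the result with the package's own flatness convention (plateau
  # between the proximal 98% crossing and the distal 90% depth, 0.5 cm
  # margins), evaluated on the full curve including the distal falloff
  wl <- lapply(seq_len(nl), function(i) {
    l <- layers[[i]]
    energy_layer(l$mean_energy, l$energy_sigma, w[i], l$pullback_wet)
  })
  zchk <- seq(max(rmin - 0.5, 0.05), min(rmax + 1.2, 1.19 * rmax), by = 0.02)
  ripple <- tryCatch(
    distal_metrics(sobp_analytic(wl, zchk, model, nuclear))$flatness,
    error = function(e) NA_real_)
  if (is.na(ripple)) {
    sob <- basis %*% w
    ripple <- 100 * (max(sob) - min(sob)) / 2 / mean(sob)
  }
  if (ripple > flatness_target)
    stop(sprintf(paste0("weight optimisation did not reach the flatness ",
                        "target: ripple %.2f%% exceeds %.1f%%; the layer ",
                        "spacing is too coarse for the layer energy spreads"),
                 ripple, flatness_target), call. = FALSE)
  w
}

#' Scale the shallowest layer's weight (start-angle trim)
#'
#' The wheel's start angle effectively shortens the first (thickest-pullback)
#' step; varying it trims the shallowest layer's weight. Scales that weight
#' by `1 + delta` and renormalises.
#'
#' @param weights weight vector ordered deepest-first (shallowest last).
#' @param delta fractional change, > -1.
#' @return Renormalised weight vector.
#' @export
adjust_first_layer <- function(weights, delta) {
  if (delta < -1) stop("delta must be > -1 (weight would go negative)",
                       call. = FALSE)
  n <- length(weights)
  weights[n] <- weights[n] * (1 + delta)
  if (sum(weights) <= 0) stop("weights sum to zero after adjustment",
                              call. = FALSE)
  weights / sum(weights)
}

#' Assemble a full SOBP source model
#'
#' Builds the three-component source for a prescribed range and modulation:
#' discrete energy layers, per-layer weights, and per-layer energy spreads,
#' together with the source disk geometry and the lead-foil thickness. When
#' no [machine_config()] is supplied, weights come from [optimize_weights()]
#' against the analytic oracle (the package's replacement for the vendor
#' spreadsheet); with a machine table they come from
#' [weights_from_modulation()].
#'
#' With `calibrate_range = TRUE` (default) the source is commissioned against
#' the analytic oracle, deterministically: the deepest layer's energy is
#' adjusted so the pristine distal 90% depth equals the nominal range, and
#' the pullback span is adjusted so the SOBP's proximal-to-distal 90%
#' distance equals the nominal modulation (the vendor convention in which
#' "modulation" is the 90%-to-90% extent, not the flat-top width). This
#' mirrors the commissioning step of fitting the source description to the
#' measured beam rather than to bare model constants.
#'
#' @param nominal_range prescribed range (distal r90) in cm water.
#' @param nominal_modulation prescribed modulation width in cm water.
#' @param layer_spacing layer pullback spacing in cm water; `NULL` (default)
#'   chooses it adaptively as 1.1 times the deepest layer's Gaussian range
#'   spread (capped at 0.5 cm, floored at 0.15 cm). Pullback steps wider than
#'   the pristine-peak width alias into plateau ripple no weight choice can
#'   remove, so the spacing must track the energy spread model.
#' @param foil_thickness_mm lead foil thickness in mm (default 2).
#' @param disk_diameter source disk diameter in cm (default 2.7).
#' @param angular_spread_deg half-cone angular spread in degrees
#'   (default 3.44).
#' @param source_to_isocenter source plane distance upstream of isocenter in
#'   cm (default 230).
#' @param machine optional [machine_config()].
#' @param start_angle_delta fractional trim of the shallowest layer's weight
#'   (see [adjust_first_layer()]; default 0).
#' @param model a [range_energy_model()].
#' @param materials material table (for the foil WET).
#' @param nuclear a [nuclear_policy()] passed to the oracle.
#' @param entrance_sigma_fn,straggling_fn see [compute_layer_sigma()].
#' @param calibrate_range logical; calibrate the deepest layer to the oracle
#'   r90 (default `TRUE`).
#' @return Object of class `pmc_source`: the layer list (source-side
#'   energies), geometry, foil, and the beam prescription.
#' @examples
#' \donttest{
#' src <- source_model(8, 5)
#' length(src$layers)
#' }
#' @export
source_model <- function(nominal_range, nominal_modulation,
                         layer_spacing = NULL, foil_thickness_mm = 2,
                         disk_diameter = 2.7, angular_spread_deg = 3.44,
                         source_to_isocenter = 230, machine = NULL,
                         start_angle_delta = 0,
                         model = range_energy_model(),
                         materials = pmc_materials(),
                         nuclear = nuclear_policy(),
                         entrance_sigma_fn = entrance_sigma_default,
                         straggling_fn = range_straggling_sigma_default,
                         calibrate_range = TRUE) {
  stopifnot(disk_diameter > 0, angular_spread_deg > 0, angular_spread_deg < 90,
            source_to_isocenter > 0, foil_thickness_mm >= 0)
  if (nominal_modulation > nominal_range)
    stop("modulation cannot exceed range", call. = FALSE)
  foil_wet_cm <- wet(foil_thickness_mm / 10, materials$lead)

  range_used <- nominal_range
  if (calibrate_range) {
    # one fixed-point pass: shift so the oracle's pristine distal r90 of the
    # deepest layer lands on the nominal range
    for (it in 1:2) {
      e0 <- energy_from_range(range_used + foil_wet_cm, model)
      ew <- energy_from_range(range_used, model)
      sg <- compute_layer_sigma(e0, entrance_sigma_fn, straggling_fn)
      zs <- seq(max(range_used - 3, 0),
                min(range_used + 1.5, 1.19 * range_from_energy(ew, model)),
                by = 0.02)
      pb <- pristine_bragg(analytic_beam(ew, sg), zs, model, nuclear)
      r90 <- distal_metrics(pb)$r90
      range_used <- range_used + (nominal_range - r90)
    }
  }

  if (is.null(layer_spacing)) {
    # keep the pullback step near the deepest pristine peak's Gaussian width
    # so the plateau does not ripple at the step period
    ew <- energy_from_range(max(range_used, 0.5), model)
    sgE <- compute_layer_sigma(energy_from_range(range_used + foil_wet_cm,
                                                 model),
                               entrance_sigma_fn, straggling_fn)
    sz <- sqrt((sgE / stopping_power(ew, model = model))^2 +
                 .intrinsic_range_variance(range_used, model, 0.087))
    layer_spacing <- min(0.5, max(0.15, 1.1 * sz))
    if (nominal_modulation > 0)
      layer_spacing <- min(layer_spacing, nominal_modulation)
  }

  # Mean depth-projection deficit from oblique incidence: protons leave the
  # foil with <theta^2> = 2 sigma_f^2 (two scattering axes) on top of the
  # source cone's <theta^2> ~= alpha^2/2, so their stopping depth along z is
  # shorter than their range by about R <theta^2> / 2. Commissioning folds
  # this into the layer energies, as fitting to measured depth doses would.
  cone_t2 <- (angular_spread_deg * pi / 180)^2 / 2
  obliquity_pullup <- function(r_water) {
    if (!calibrate_range || r_water <= 0) return(0)
    e_exit <- energy_from_range(r_water, model)
    sf <- if (foil_thickness_mm > 0)
      highland_sigma(e_exit, foil_thickness_mm / 10 * materials$lead$mass_density,
                     materials$lead$radiation_length) else 0
    r_water * (2 * sf^2 + cone_t2) / 2
  }

  build_once <- function(mod_used) {
    layers <- build_energy_layers(range_used, mod_used, layer_spacing,
                                  foil_wet_cm, machine, model,
                                  entrance_sigma_fn, straggling_fn)
    if (is.null(machine)) {
      eff <- .strip_foil(layers, foil_wet_cm, model)
      w <- if (length(layers) == 1L) 1 else optimize_weights(eff, model, nuclear)
    } else {
      w <- weights_from_modulation(machine)
      if (length(w) != length(layers))
        stop("machine table and layer count disagree", call. = FALSE)
    }
    for (i in seq_along(layers)) layers[[i]]$weight <- w[i]
    layers
  }

  mod_used <- nominal_modulation
  layers <- build_once(mod_used)
  if (calibrate_range && is.null(machine) && nominal_modulation > 0 &&
      nominal_modulation < nominal_range) {
    # commission the pullback span so the oracle SOBP's proximal-to-distal
    # 90% distance reproduces the prescribed modulation
    for (it in 1:6) {
      zs <- seq(0.05, min(nominal_range + 1.2, 1.19 * nominal_range),
                by = 0.02)
      sob <- sobp_analytic(.strip_foil(layers, foil_wet_cm, model), zs,
                           model, nuclear)
      mt <- distal_metrics(sob)
      err_r <- mt$r90 - nominal_range
      err_m <- mt$modulation - nominal_modulation
      if (abs(err_r) < 0.02 && abs(err_m) < 0.02) break
      range_used <- range_used - err_r
      mod_used <- min(max(mod_used - err_m, layer_spacing), nominal_range)
      layers <- build_once(mod_used)
    }
  }
  if (start_angle_delta != 0) {
    w <- adjust_first_layer(vapply(layers, `[[`, numeric(1), "weight"),
                            start_angle_delta)
    for (i in seq_along(layers)) layers[[i]]$weight <- w[i]
  }

  # fold the obliquity compensation into the sampled (source-side) energies;
  # effective_layers() removes it again so the oracle keeps describing the
  # beam's depth behaviour, not its slant path
  layers <- lapply(layers, function(l) {
    rw <- range_from_energy(l$mean_energy, model) - foil_wet_cm
    du <- obliquity_pullup(rw)
    if (du > 0)
      l$mean_energy <- energy_from_range(rw + du + foil_wet_cm, model)
    l$obliquity_wet <- du
    l
  })

  structure(list(layers = layers,
                 disk_diameter = disk_diameter,
                 angular_spread_deg = angular_spread_deg,
                 source_to_isocenter = source_to_isocenter,
                 foil_thickness_mm = foil_thickness_mm,
                 foil_wet_cm = foil_wet_cm,
                 nominal_range = nominal_range,
                 nominal_modulation = nominal_modulation),
            class = "pmc_source")
}

#' @export
print.pmc_source <- function(x, ...) {
  cat(sprintf(paste0("<pmc_source> range %.2f / mod %.2f cm; %d layers; ",
                     "foil %.2f mm Pb; disk %.2f cm; spread %.2f deg\n"),
              x$nominal_range, x$nominal_modulation, length(x$layers),
              x$foil_thickness_mm, x$disk_diameter, x$angular_spread_deg))
  invisible(x)
}

.strip_foil <- function(layers, foil_wet_cm, model) {
  lapply(layers, function(l) {
    r <- range_from_energy(l$mean_energy, model) - foil_wet_cm
    if (r <= 0) stop("foil absorbs an entire layer", call. = FALSE)
    energy_layer(energy_from_range(r, model), l$energy_sigma, l$weight,
                 l$pullback_wet)
  })
}

#' Layers as seen in water (foil and obliquity pullback folded in)
#'
#' Source layers describe the beam upstream of the lead foil, including the
#' commissioning compensation for oblique incidence. This helper subtracts
#' both the foil's WET and the obliquity allowance from every layer's range,
#' yielding the in-water depth description needed by the analytic oracle.
#'
#' @param source a [source_model()].
#' @param model a [range_energy_model()].
#' @return List of [energy_layer()].
#' @export
effective_layers <- function(source, model = range_energy_model()) {
  stopifnot(inherits(source, "pmc_source"))
  lapply(source$layers, function(l) {
    r <- range_from_energy(l$mean_energy, model) - source$foil_wet_cm -
      (l$obliquity_wet %||% 0)
    if (r <= 0) stop("foil absorbs an entire layer", call. = FALSE)
    energy_layer(energy_from_range(r, model), l$energy_sigma, l$weight,
                 l$pullback_wet)
  })
}

#' Sample proton initial states from a source
#'
#' Positions are uniform on the source disk at `z = -source_to_isocenter`;
#' directions are uniform in solid angle within the half-cone
#' `angular_spread_deg` about +z; the layer is chosen with probability equal
#' to its weight; the energy is Gaussian about the layer mean. Draw order is
#' fixed (layer, disk radius, disk azimuth, cone polar, cone azimuth,
#' energy), so a given seed reproduces the sample bit for bit.
#'
#' @param source a [source_model()].
#' @param n number of protons (>= 1).
#' @param seed optional integer passed to `set.seed()`.
#' @return A [proton_states()] collection.
#' @export
sample_source <- function(source, n, seed = NULL) {
  stopifnot(inherits(source, "pmc_source"), n >= 1)
  if (length(source$layers) == 0L) stop("source has no layers", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- vapply(source$layers, `[[`, numeric(1), "weight")
  if (any(is.na(w))) stop("layer weights are unset", call. = FALSE)

  li <- sample.int(length(w), n, replace = TRUE, prob = w)
  r <- source$disk_diameter / 2 * sqrt(stats::runif(n))
  ph <- stats::runif(n, 0, 2 * pi)
  cmin <- cos(source$angular_spread_deg * pi / 180)
  ct <- stats::runif(n, cmin, 1)
  ps <- stats::runif(n, 0, 2 * pi)
  mu <- vapply(source$layers, `[[`, numeric(1), "mean_energy")[li]
  sg <- vapply(source$layers, `[[`, numeric(1), "energy_sigma")[li]
  e <- stats::rnorm(n, mu, sg)
  e <- pmax(e, 0.5)  # guard against unphysical negative tails

  st <- sqrt(1 - ct^2)
  proton_states(x = r * cos(ph), y = r * sin(ph),
                z = rep(-source$source_to_isocenter, n),
                ux = st * cos(ps), uy = st * sin(ps), uz = ct,
                energy = e)
}

#' Serialise a source model to JSON / read it back
#'
#' Layers are stored as a table of energy, weight, sigma and pullback,
#' alongside the disk geometry and beam prescription.
#'
#' @param source a [source_model()].
#' @param path file path.
#' @export
write_source_model <- function(source, path) {
  stopifnot(inherits(source, "pmc_source"))
  doc <- list(
    nominal_range = source$nominal_range,
    nominal_modulation = source$nominal_modulation,
    disk_diameter = source$disk_diameter,
    angular_spread_deg = source$angular_spread_deg,
    source_to_isocenter = source$source_to_isocenter,
    foil_thickness_mm = source$foil_thickness_mm,
    foil_wet_cm = source$foil_wet_cm,
    layers = data.frame(
      mean_energy = vapply(source$layers, `[[`, numeric(1), "mean_energy"),
      weight = vapply(source$layers, `[[`, numeric(1), "weight"),
      energy_sigma = vapply(source$layers, `[[`, numeric(1), "energy_sigma"),
      pullback_wet = vapply(source$layers, `[[`, numeric(1), "pullback_wet")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_source_model
#' @export
read_source_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow(doc$layers)), function(i)
    energy_layer(doc$layers$mean_energy[i], doc$layers$energy_sigma[i],
                 doc$layers$weight[i], doc$layers$pullback_wet[i]))
  structure(list(layers = layers,
                 disk_diameter = doc$disk_diameter,
                 angular_spread_deg = doc$angular_spread_deg,
                 source_to_isocenter = doc$source_to_isocenter,
                 foil_thickness_mm = doc$foil_thickness_mm,
                 foil_wet_cm = doc$foil_wet_cm,
                 nominal_range = doc$nominal_range,
                 nominal_modulation = doc$nominal_modulation),
            class = "pmc_source")
}

#' Export the layer table as CSV (energy, weight, sigma)
#'
#' @param source a [source_model()].
#' @param path file path.
#' @export
export_layer_table <- function(source, path) {
  stopifnot(inherits(source, "pmc_source"))
  utils::write.csv(data.frame(
    energy_mev = vapply(source$layers, `[[`, numeric(1), "mean_energy"),
    weight = vapply(source$layers, `[[`, numeric(1), "weight"),
    sigma_t_mev = vapply(source$layers, `[[`, numeric(1), "energy_sigma")),
    path, row.names = FALSE)
  invisible(path)
}
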