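#' Collection of proton states
#'
#' Column-vector representation of a set of protons: position (cm), unit
#' direction, kinetic energy (MeV), statistical weight and an alive flag.
#' All beamline and transport operators act on whole collections at once.
#'
#' @param x,y,z positions in cm.
#' @param ux,uy,uz direction components; each row must be unit within 1e-9.
#' @param energy kinetic energies in MeV, >= 0.
#' @param weight statistical weights, > 0 (default 1).
#' @param alive logical liveness flags (default all `TRUE`).
#' @return Object of class `pmc_proton_states`.
#' @export
proton_states <- function(x, y, z, ux, uy, uz, energy,
                          weight = rep(1, length(x)),
                          alive = rep(TRUE, length(x))) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, length(ux) == n,
            length(uy) == n, length(uz) == n, length(energy) == n,
            length(weight) == n, length(alive) == n)
  nrm <- ux^2 + uy^2 + uz^2
  if (any(abs(nrm - 1) > 1e-9))
    stop("directions must be unit vectors (|u| = 1 within 1e-9)", call. = FALSE)
  if (any(energy < 0)) stop("kinetic energy must be >= 0", call. = FALSE)
  if (any(weight <= 0)) stop("statistical weight must be > 0", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 ux = as.numeric(ux), uy = as.numeric(uy), uz = as.numeric(uz),
                 energy = as.numeric(energy), weight = as.numeric(weight),
                 alive = as.logical(alive)),
            class = "pmc_proton_states")
}

#' @export
print.pmc_proton_states <- function(x, ...) {
  cat(sprintf("<pmc_proton_states> %d protons (%d alive), E in [%.3g, %.3g] MeV\n",
              length(x$x), sum(x$alive),
              min(x$energy[x$alive]), max(x$energy[x$alive])))
  invisible(x)
}

#' Number of protons in a collection
#' @param states a [proton_states()] collection.
#' @export
n_protons <- function(states) length(states$x)

.subset_states <- function(states, keep) {
  for (f in c("x", "y", "z", "ux", "uy", "uz", "energy", "weight", "alive"))
    states[[f]] <- states[[f]][keep]
  states
}

#' Highland multiple-Coulomb-scattering sigma
#'
#' `sigma = 14.1 MeV / pv * sqrt(x/X0) * (1 + log10(x/X0)/9)` radians, the
#' standard parameterisation of the projected MCS angle, with
#' `pv = E (E + 2 m_p) / (E + m_p)`. Returns 0 for zero path length.
#'
#' @param energy_mev proton kinetic energy in MeV (> 0), vectorised.
#' @param path_gcm2 traversed areal density in g/cm^2 (>= 0), vectorised.
#' @param x0_gcm2 radiation length of the medium in g/cm^2.
#' @return Scattering sigma in radians.
#' @examples
#' highland_sigma(100, 0.01 * 36.08, 36.08) # about 5.8 mrad
#' @export
highland_sigma <- function(energy_mev, path_gcm2, x0_gcm2) {
  if (any(energy_mev <= 0)) stop("energy must be > 0", call. = FALSE)
  if (any(path_gcm2 < 0)) stop("path must be >= 0", call. = FALSE)
  mp <- 938.272
  pv <- energy_mev * (energy_mev + 2 * mp) / (energy_mev + mp)
  t <- path_gcm2 / x0_gcm2
  s <- ifelse(t > 0,
              14.1 / pv * sqrt(t) * (1 + log10(pmax(t, 1e-300)) / 9),
              0)
  pmax(s, 0)
}

# Gaussian angular kick of per-particle sigma (radians) applied to unit
# direction vectors; small-angle addition in the local transverse frame.
.deflect <- function(ux, uy, uz, sigma) {
  n <- length(ux)
  tx <- stats::rnorm(n) * sigma
  ty <- stats::rnorm(n) * sigma
  # transverse basis: u = normalize((-uy, ux, 0)), fallback (1,0,0) when
  # the direction is (anti)parallel to z; v = d x u
  pn <- sqrt(ux^2 + uy^2)
  degen <- pn < 1e-12
  e1x <- ifelse(degen, 1, -uy / pn)
  e1y <- ifelse(degen, 0, ux / pn)
  e1z <- 0
  e2x <- uy * e1z - uz * e1y
  e2y <- uz * e1x - ux * e1z
  e2z <- ux * e1y - uy * e1x
  nx <- ux + tx * e1x + ty * e2x
  ny <- uy + tx * e1y + ty * e2y
  nz <- uz + tx * e1z + ty * e2z
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  list(ux = nx / nn, uy = ny / nn, uz = nz / nn)
}

#' Step-length policy
#'
#' @param max_step_cm hard cap on the geometric step (default 0.1 cm,
#'   matching 1 mm scoring).
#' @param range_fraction cap as a fraction of the residual physical range
#'   (default 0.2), so steps shrink near the end of range.
#' @param min_step_cm floor preventing stalls at boundaries (default 2e-4).
#' @export
step_policy <- function(max_step_cm = 0.1, range_fraction = 0.2,
                        min_step_cm = 2e-4) {
  stopifnot(max_step_cm > 0, range_fraction > 0, range_fraction <= 1,
            min_step_cm > 0)
  list(max_step_cm = max_step_cm, range_fraction = range_fraction,
       min_step_cm = min_step_cm)
}

#' Simplified nuclear interaction policy
#'
#' Primaries are removed with probability `1 - exp(-lambda * step_wet)`; a
#' removed proton deposits `local_fraction` of its remaining energy in the
#' current voxel, the rest is booked as escaped. A declared stand-in for full
#' hadronic physics.
#'
#' @param lambda removal rate per cm of water (default 0.012).
#' @param local_fraction locally deposited energy fraction (default 0.6).
#' @export
nuclear_policy <- function(lambda = 0.012, local_fraction = 0.6) {
  stopifnot(lambda >= 0, local_fraction >= 0, local_fraction <= 1)
  list(lambda = lambda, local_fraction = local_fraction)
}

# distance to the next clamp-grid plane along the direction of flight.
# For homogeneous phantoms the clamp grid degenerates to the outer box.
.boundary_distance <- function(x, y, z, ux, uy, uz, origin, voxel, dims,
                               uniform) {
  big <- 1e30
  dist_axis <- function(p, u, o, dv, n) {
    if (uniform) {
      hi <- o + n * dv
      t <- ifelse(u > 0, (hi - p) / u, ifelse(u < 0, (o - p) / u, big))
    } else {
      idx <- floor((p - o) / dv)
      t <- ifelse(u > 0, (o + (idx + 1) * dv - p) / u,
                  ifelse(u < 0, (o + idx * dv - p) / u, big))
    }
    pmax(t, 0)
  }
  pmin(dist_axis(x, ux, origin[1], voxel[1], dims[1]),
       dist_axis(y, uy, origin[2], voxel[2], dims[2]),
       dist_axis(z, uz, origin[3], voxel[3], dims[3]))
}

#' Proposed step lengths for a proton collection
#'
#' The condensed-history step is the minimum of the policy's hard cap, the
#' range-fraction cap, and the distance to the next voxel boundary of the
#' phantom (so no step crosses more than one material boundary), with a small
#' floor to guarantee progress.
#'
#' @param states a [proton_states()] collection (alive protons).
#' @param phantom_obj a [phantom()].
#' @param policy a [step_policy()].
#' @param model a [range_energy_model()].
#' @param materials material table from [pmc_materials()].
#' @return Numeric vector of step lengths (cm), one per proton.
#' @export
step_length <- function(states, phantom_obj, policy = step_policy(),
                        model = range_energy_model(),
                        materials = pmc_materials()) {
  uniform <- is.null(phantom_obj$material_index) &&
    is.null(phantom_obj$density_override)
  rsp <- vapply(phantom_obj$materials, function(m)
    materials[[m]]$relative_stopping_power, numeric(1))
  mat_id <- if (uniform) rep(1L, n_protons(states)) else
    .material_at(states$x, states$y, states$z, phantom_obj)
  mat_id[mat_id == 0L] <- 1L
  r_phys <- range_from_energy(states$energy, model) / rsp[mat_id]
  tb <- .boundary_distance(states$x, states$y, states$z,
                           states$ux, states$uy, states$uz,
                           phantom_obj$origin, phantom_obj$voxel,
                           phantom_obj$dims, uniform)
  pmax(pmin(policy$max_step_cm, policy$range_fraction * r_phys, tb + 1e-7),
       policy$min_step_cm)
}

# material id at positions; 0 = outside the phantom box
.material_at <- function(x, y, z, ph) {
  i <- floor((x - ph$origin[1]) / ph$voxel[1])
  j <- floor((y - ph$origin[2]) / ph$voxel[2])
  k <- floor((z - ph$origin[3]) / ph$voxel[3])
  inside <- i >= 0 & i < ph$dims[1] & j >= 0 & j < ph$dims[2] &
    k >= 0 & k < ph$dims[3]
  out <- integer(length(x))
  if (is.null(ph$material_index)) {
    out[inside] <- 1L
  } else {
    lin <- 1L + i[inside] + ph$dims[1] * (j[inside] + ph$dims[2] * k[inside])
    out[inside] <- ph$material_index[lin]
  }
  out
}

.density_factor_at <- function(x, y, z, ph, rho_nominal, mat_id) {
  if (is.null(ph$density_override)) return(rep(1, length(x)))
  i <- floor((x - ph$origin[1]) / ph$voxel[1])
  j <- floor((y - ph$origin[2]) / ph$voxel[2])
  k <- floor((z - ph$origin[3]) / ph$voxel[3])
  lin <- 1L + i + ph$dims[1] * (j + ph$dims[2] * k)
  ph$density_override[lin] / rho_nominal[mat_id]
}

#' Condensed-history transport through a voxelised phantom
#'
#' Transports a collection of protons through `phantom_obj`, scoring energy
#' deposits on `mesh`. Per step: continuous energy loss from the
#' Bragg-Kleeman model (water-equivalent tracking via the local material's
#' RSP) with Gaussian straggling of variance `bohr_coeff * step_wet`;
#' Highland-sigma Gaussian deflection; exponential nuclear removal of
#' primaries per `nuclear`; deposit-on-kill below `cutoff_mev`. Deposits are
#' binned at the step midpoint. Histories are split into `n_batches` batches
#' whose per-voxel sums and squared sums feed [estimate_uncertainty()].
#'
#' Energy bookkeeping is exact: launched = deposited + escaped, where
#' escaped counts protons leaving the phantom plus the non-local fraction of
#' nuclear removals (deposits falling outside the scoring mesh still count as
#' deposited in the phantom).
#'
#' Randomness is drawn from R's global RNG stream; call `set.seed()` (or use
#' the `seed` argument) for reproducible runs. Draws occur in a fixed
#' documented order per step: straggling, nuclear, two scattering angles.
#'
#' @param states a [proton_states()] collection at (or upstream of) the
#'   phantom entry face; protons upstream are propagated ballistically to it.
#' @param phantom_obj a [phantom()].
#' @param mesh a [dose_grid()] scoring mesh; default: one matching the
#'   phantom grid.
#' @param materials material table from [pmc_materials()].
#' @param model a [range_energy_model()].
#' @param policy a [step_policy()].
#' @param nuclear a [nuclear_policy()].
#' @param cutoff_mev tracking cutoff (default 0.5 MeV); the remainder is
#'   deposited locally.
#' @param bohr_coeff energy-straggling variance rate in MeV^2 per cm of
#'   water-equivalent path (default 0.087, the Bohr value for water).
#' @param n_batches number of statistical batches (default 10).
#' @param seed optional integer; when given, `set.seed(seed)` is called first.
#' @return The filled `pmc_dose_grid`.
#' @export
transport_in_phantom <- function(states, phantom_obj, mesh = NULL,
                                 materials = pmc_materials(),
                                 model = range_energy_model(),
                                 policy = step_policy(),
                                 nuclear = nuclear_policy(),
                                 cutoff_mev = 0.5, bohr_coeff = 0.087,
                                 n_batches = 10L, seed = NULL) {
  stopifnot(inherits(states, "pmc_proton_states"),
            inherits(phantom_obj, "pmc_phantom"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mesh))
    mesh <- dose_grid(phantom_obj$origin, phantom_obj$voxel, phantom_obj$dims)

  keep <- states$alive
  states <- .subset_states(states, keep)
  n <- n_protons(states)
  if (n == 0L) stop("no alive protons to transport", call. = FALSE)

  # ballistic propagation to the phantom entry face for upstream protons
  zface <- phantom_obj$origin[3]
  up <- states$z < zface
  if (any(up)) {
    if (any(states$uz[up] <= 0))
      stop("upstream protons must travel toward the phantom (+z)", call. = FALSE)
    t <- (zface - states$z[up]) / states$uz[up]
    states$x[up] <- states$x[up] + t * states$ux[up]
    states$y[up] <- states$y[up] + t * states$uy[up]
    states$z[up] <- zface + 1e-9
  }

  rsp_tab <- vapply(phantom_obj$materials, function(m)
    materials[[m]]$relative_stopping_power, numeric(1))
  rho_tab <- vapply(phantom_obj$materials, function(m)
    materials[[m]]$mass_density, numeric(1))
  x0_tab <- vapply(phantom_obj$materials, function(m)
    materials[[m]]$radiation_length, numeric(1))

  n_batches <- max(1L, min(as.integer(n_batches), n))
  batch_of <- sort(rep_len(seq_len(n_batches), n))  # contiguous history chunks

  launched <- sum(states$weight * states$energy)
  deposited <- 0
  escaped <- 0
  n_escaped <- 0L
  nvox <- prod(mesh$dims)

  for (b in seq_len(n_batches)) {
    sel <- batch_of == b
    st <- .subset_states(states, sel)
    res <- .transport_batch(st, phantom_obj, mesh, rsp_tab, rho_tab, x0_tab,
                            model, policy, nuclear, cutoff_mev, bohr_coeff)
    mesh$deposit <- mesh$deposit + res$dep
    mesh$deposit_sq <- mesh$deposit_sq + res$dep^2
    deposited <- deposited + res$deposited
    escaped <- escaped + res$escaped
    n_escaped <- n_escaped + res$n_escaped
  }

  mesh$histories <- mesh$histories + n
  mesh$n_batches <- mesh$n_batches + n_batches
  mesh$launched_energy <- mesh$launched_energy + launched
  mesh$deposited_energy <- mesh$deposited_energy + deposited
  mesh$escaped_energy <- mesh$escaped_energy + escaped
  mesh$n_escaped <- mesh$n_escaped + n_escaped
  mesh
}

.transport_batch <- function(st, ph, mesh, rsp_tab, rho_tab, x0_tab,
                             model, policy, nuclear, cutoff_mev, bohr_coeff) {
  uniform <- is.null(ph$material_index) && is.null(ph$density_override)
  dep <- numeric(prod(mesh$dims))
  deposited <- 0
  escaped <- 0
  n_escaped <- 0L
  alpha <- model$alpha; p <- model$p
  mo <- mesh$origin; mv <- mesh$voxel; md <- mesh$dims

  x <- st$x; y <- st$y; z <- st$z
  ux <- st$ux; uy <- st$uy; uz <- st$uz
  e <- st$energy; w <- st$weight

  score <- function(xm, ym, zm, de) {
    deposited <<- deposited + sum(de)
    i <- floor((xm - mo[1]) / mv[1])
    j <- floor((ym - mo[2]) / mv[2])
    k <- floor((zm - mo[3]) / mv[3])
    ok <- i >= 0 & i < md[1] & j >= 0 & j < md[2] & k >= 0 & k < md[3] & de > 0
    if (!any(ok)) return(invisible())
    lin <- 1 + i[ok] + md[1] * (j[ok] + md[2] * k[ok])
    tab <- rowsum(de[ok], lin)
    ii <- as.integer(rownames(tab))
    dep[ii] <<- dep[ii] + tab[, 1]
    invisible()
  }

  while (length(x) > 0L) {
    mat <- .material_at(x, y, z, ph)
    out <- mat == 0L
    if (any(out)) {
      escaped <- escaped + sum(w[out] * e[out])
      n_escaped <- n_escaped + sum(out)
      keep <- !out
      x <- x[keep]; y <- y[keep]; z <- z[keep]
      ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]
      e <- e[keep]; w <- w[keep]; mat <- mat[keep]
      if (length(x) == 0L) break
    }
    rsp <- rsp_tab[mat]
    rho <- rho_tab[mat]
    if (!is.null(ph$density_override)) {
      f <- .density_factor_at(x, y, z, ph, rho_tab, mat)
      rsp <- rsp * f
      rho <- rho * f
    }
    rw <- alpha * e^p
    tb <- .boundary_distance(x, y, z, ux, uy, uz, ph$origin, ph$voxel,
                             ph$dims, uniform)
    L <- pmax(pmin(policy$max_step_cm, policy$range_fraction * rw / rsp,
                   tb + 1e-7),
              policy$min_step_cm)
    lwet <- L * rsp

    xm <- x + 0.5 * L * ux
    ym <- y + 0.5 * L * uy
    zm <- z + 0.5 * L * uz

    # continuous energy loss + Gaussian straggling (draw 1)
    rw2 <- rw - lwet
    stopped <- rw2 <= 0
    e2 <- numeric(length(e))
    e2[!stopped] <- (rw2[!stopped] / alpha)^(1 / p)
    de <- e - e2
    de <- de + stats::rnorm(length(e)) * sqrt(bohr_coeff * lwet)
    de <- pmin(pmax(de, 0), e)
    de[stopped] <- e[stopped]
    enew <- e - de
    enew[stopped] <- 0
    score(xm, ym, zm, w * de)

    # nuclear removal (draw 2)
    prem <- 1 - exp(-nuclear$lambda * lwet)
    nuked <- stats::runif(length(e)) < prem & !stopped & enew > 0
    if (any(nuked)) {
      score(xm[nuked], ym[nuked], zm[nuked],
            w[nuked] * enew[nuked] * nuclear$local_fraction)
      escaped <- escaped +
        sum(w[nuked] * enew[nuked] * (1 - nuclear$local_fraction))
    }

    # tracking cutoff: deposit the remainder where the proton ends up
    x2 <- x + L * ux; y2 <- y + L * uy; z2 <- z + L * uz
    cut <- !stopped & !nuked & enew < cutoff_mev & enew > 0
    if (any(cut)) score(x2[cut], y2[cut], z2[cut], w[cut] * enew[cut])

    dead <- stopped | nuked | cut | enew <= 0

    # multiple Coulomb scattering for survivors (draws 3 and 4)
    live <- which(!dead)
    if (length(live) > 0L) {
      sig <- highland_sigma(e[live], L[live] * rho[live], x0_tab[mat[live]])
      nd <- .deflect(ux[live], uy[live], uz[live], sig)
      ux[live] <- nd$ux; uy[live] <- nd$uy; uz[live] <- nd$uz
    }

    x <- x2[live]; y <- y2[live]; z <- z2[live]
    ux <- ux[live]; uy <- uy[live]; uz <- uz[live]
    e <- enew[live]; w <- w[live]
  }

  list(dep = array(dep, mesh$dims), deposited = deposited, escaped = escaped,
       n_escaped = n_escaped)
}

#' Statistical uncertainty of a dose grid
#'
#' Per-voxel relative standard error of the mean dose, computed from the
#' per-batch sums and squared sums; the region value is the mean over voxels
#' receiving more than `region_threshold` of the maximum dose.
#'
#' @param dose a filled `pmc_dose_grid` with at least 2 batches.
#' @param region_threshold fraction of max dose defining the high-dose region
#'   (default 0.5).
#' @return list with `region` (mean relative SEM over the region) and
#'   `per_voxel` (array of relative SEMs, NA where dose is 0).
#' @export
estimate_uncertainty <- function(dose, region_threshold = 0.5) {
  stopifnot(inherits(dose, "pmc_dose_grid"))
  b <- dose$n_batches
  if (b < 2L) stop("need at least 2 batches/histories", call. = FALSE)
  s <- dose$deposit
  q <- dose$deposit_sq
  varb <- pmax(q - s^2 / b, 0) / (b - 1)
  sem <- sqrt(varb / b)            # SEM of the per-batch mean
  rel <- array(NA_real_, dim(s))
  nz <- s > 0
  rel[nz] <- sem[nz] / (s[nz] / b)
  mx <- max(s)
  if (mx <= 0) stop("dose grid is empty", call. = FALSE)
  sel <- s > region_threshold * mx
  list(region = mean(rel[sel]), per_voxel = rel)
}
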