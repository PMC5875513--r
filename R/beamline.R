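#' Simplified nozzle geometry
#'
#' The whole treatment head is reduced to an absorbing metallic cylinder with
#' a single lead foil halfway between the source plane and the nozzle exit.
#' Protons whose straight path lies beyond the inner radius at the exit plane
#' are terminated (the wall is a perfect absorber).
#'
#' @param inner_radius inner cylinder radius in cm (default 13).
#' @param wall_thickness wall thickness in cm (default 6; only documented,
#'   the wall absorbs perfectly regardless).
#' @param exit_z z of the nozzle exit plane in cm (default -50; isocenter is
#'   z = 0, source at negative z).
#' @param foil_thickness_mm lead foil thickness in mm.
#' @return Object of class `pmc_nozzle`.
#' @export
nozzle_geometry <- function(inner_radius = 13, wall_thickness = 6,
                            exit_z = -50, foil_thickness_mm = 2) {
  stopifnot(inner_radius > 0, wall_thickness > 0, foil_thickness_mm >= 0)
  structure(list(inner_radius = inner_radius, wall_thickness = wall_thickness,
                 exit_z = exit_z, foil_thickness_mm = foil_thickness_mm),
            class = "pmc_nozzle")
}

#' Propagate protons ballistically to a z plane
#'
#' Straight-line drift (vacuum) of all alive protons to `z_plane`; dead
#' protons are left untouched.
#'
#' @param states a [proton_states()] collection.
#' @param z_plane target plane in cm; must be downstream of every alive
#'   proton.
#' @return Updated collection.
#' @export
propagate_to_plane <- function(states, z_plane) {
  a <- states$alive
  if (any(states$uz[a] <= 0))
    stop("cannot propagate protons moving backwards", call. = FALSE)
  t <- (z_plane - states$z[a]) / states$uz[a]
  if (any(t < -1e-9)) stop("plane is upstream of an alive proton", call. = FALSE)
  states$x[a] <- states$x[a] + t * states$ux[a]
  states$y[a] <- states$y[a] + t * states$uy[a]
  states$z[a] <- z_plane
  states
}

#' Traverse the lead scattering foil
#'
#' Thin-plane operator: every alive proton loses the foil's water-equivalent
#' thickness from its residual range and receives a Gaussian angular kick
#' with the Highland sigma for that thickness of lead. Protons whose range
#' is exhausted are marked dead. A zero-thickness foil is the identity (and
#' consumes no random numbers).
#'
#' @param states a [proton_states()] collection at the foil plane.
#' @param foil_thickness_mm foil thickness in mm lead (>= 0).
#' @param materials material table containing `lead`.
#' @param model a [range_energy_model()].
#' @return Updated collection.
#' @export
traverse_foil <- function(states, foil_thickness_mm,
                          materials = pmc_materials(),
                          model = range_energy_model()) {
  if (foil_thickness_mm < 0) stop("foil thickness must be >= 0", call. = FALSE)
  if (foil_thickness_mm == 0) return(states)
  th <- foil_thickness_mm / 10
  pb <- materials$lead
  wf <- wet(th, pb)
  a <- which(states$alive)
  r2 <- range_from_energy(states$energy[a], model) - wf
  dead <- r2 <= 0
  states$alive[a[dead]] <- FALSE
  states$energy[a[dead]] <- 0
  live <- a[!dead]
  if (length(live) > 0L) {
    states$energy[live] <- energy_from_range(r2[!dead], model)
    sig <- highland_sigma(states$energy[live], th * pb$mass_density,
                          pb$radiation_length)
    nd <- .deflect(states$ux[live], states$uy[live], states$uz[live], sig)
    states$ux[live] <- nd$ux
    states$uy[live] <- nd$uy
    states$uz[live] <- nd$uz
  }
  states
}

#' Aperture constructors
#'
#' Patient-specific collimator openings: circle, rectangle, or simple
#' polygon, at a given plane. The boundary is inclusive (a proton exactly on
#' the edge passes).
#'
#' @param radius circle radius in cm (> 0).
#' @param z_position plane in cm (default -40, the snout plane).
#' @return Object of class `pmc_aperture`.
#' @export
aperture_circle <- function(radius, z_position = -40) {
  stopifnot(radius > 0)
  structure(list(shape = "circle", radius = radius, z_position = z_position),
            class = "pmc_aperture")
}

#' @rdname aperture_circle
#' @param width,height rectangle full widths in cm (> 0).
#' @export
aperture_rectangle <- function(width, height, z_position = -40) {
  stopifnot(width > 0, height > 0)
  structure(list(shape = "rectangle", width = width, height = height,
                 z_position = z_position),
            class = "pmc_aperture")
}

#' @rdname aperture_circle
#' @param vertices two-column matrix of polygon vertices in cm; must describe
#'   a simple (non-self-intersecting) polygon.
#' @export
aperture_polygon <- function(vertices, z_position = -40) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  if (.polygon_self_intersects(vertices))
    stop("polygon must be simple (non-self-intersecting)", call. = FALSE)
  structure(list(shape = "polygon", vertices = vertices,
                 z_position = z_position),
            class = "pmc_aperture")
}

.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1 else i + 1, ])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  inter <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      s1 <- seg(i); s2 <- seg(j)
      if (inter(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

.inside_aperture <- function(x, y, ap) {
  switch(ap$shape,
    circle = x^2 + y^2 <= ap$radius^2 + 1e-12,
    rectangle = abs(x) <= ap$width / 2 + 1e-12 &
                abs(y) <= ap$height / 2 + 1e-12,
    polygon = .point_in_polygon(x, y, ap$vertices))
}

# even-odd rule, boundary-inclusive to numerical tolerance
.point_in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Apply an aperture mask
#'
#' Protons at the aperture plane whose (x, y) lies inside the opening pass
#' unchanged; all others are terminated (the aperture is a perfect
#' absorber). Idempotent.
#'
#' @param states a [proton_states()] collection at the aperture plane.
#' @param ap a `pmc_aperture`.
#' @return Updated collection.
#' @export
apply_aperture <- function(states, ap) {
  stopifnot(inherits(ap, "pmc_aperture"))
  a <- states$alive
  blocked <- a & !.inside_aperture(states$x, states$y, ap)
  states$alive[blocked] <- FALSE
  states
}

#' Range compensator
#'
#' A variable-thickness absorber described by a 2D thickness map over the
#' field plane. Thickness lookup is nearest-pixel (sharp edges, no
#' interpolation); positions outside the map see zero thickness.
#'
#' @param thickness_map numeric matrix of thicknesses in cm (x by y), all
#'   >= 0.
#' @param pixel_size pixel size in cm (> 0).
#' @param origin `c(x, y)` of the map's minimum corner in cm.
#' @param material a [pmc_material()] (default Lucite).
#' @param z_position plane in cm (default -38, just downstream of the snout).
#' @return Object of class `pmc_compensator`.
#' @export
compensator <- function(thickness_map, pixel_size, origin = NULL,
                        material = pmc_materials()$lucite, z_position = -38) {
  thickness_map <- as.matrix(thickness_map)
  if (any(thickness_map < 0)) stop("thicknesses must be >= 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel size must be > 0", call. = FALSE)
  if (is.null(origin))
    origin <- -pixel_size * dim(thickness_map) / 2  # centred on the axis
  structure(list(thickness_map = thickness_map, pixel_size = pixel_size,
                 origin = as.numeric(origin), material = material,
                 z_position = z_position),
            class = "pmc_compensator")
}

#' Thickness seen at field positions (nearest-pixel lookup)
#' @param comp a [compensator()].
#' @param x,y positions in cm.
#' @return Thicknesses in cm (0 outside the map).
#' @export
compensator_thickness <- function(comp, x, y) {
  i <- floor((x - comp$origin[1]) / comp$pixel_size) + 1L
  j <- floor((y - comp$origin[2]) / comp$pixel_size) + 1L
  d <- dim(comp$thickness_map)
  th <- numeric(length(x))
  ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2]
  th[ok] <- comp$thickness_map[cbind(i[ok], j[ok])]
  th
}

#' Apply a range compensator
#'
#' Thin-plane operator: each proton's residual range drops by the WET of the
#' compensator thickness under its (x, y); it receives a Highland-sigma
#' angular kick for that thickness of the compensator material. Lateral
#' displacement inside the slab is ignored. Protons whose range is exhausted
#' are terminated.
#'
#' @param states a [proton_states()] collection at the compensator plane.
#' @param comp a [compensator()].
#' @param model a [range_energy_model()].
#' @return Updated collection.
#' @export
apply_compensator <- function(states, comp, model = range_energy_model()) {
  stopifnot(inherits(comp, "pmc_compensator"))
  a <- which(states$alive)
  th <- compensator_thickness(comp, states$x[a], states$y[a])
  hit <- th > 0
  if (!any(hit)) return(states)
  idx <- a[hit]
  wf <- wet(th[hit], comp$material)
  r2 <- range_from_energy(states$energy[idx], model) - wf
  dead <- r2 <= 0
  states$alive[idx[dead]] <- FALSE
  states$energy[idx[dead]] <- 0
  live <- idx[!dead]
  if (length(live) > 0L) {
    states$energy[live] <- energy_from_range(r2[!dead], model)
    sig <- highland_sigma(states$energy[live],
                          th[hit][!dead] * comp$material$mass_density,
                          comp$material$radiation_length)
    nd <- .deflect(states$ux[live], states$uy[live], states$uz[live], sig)
    states$ux[live] <- nd$ux
    states$uy[live] <- nd$uy
    states$uz[live] <- nd$uz
  }
  states
}

#' Run the full simplified beamline
#'
#' Applies, in order: drift to the foil plane (midway between source and
#' nozzle exit), foil traversal, drift to the nozzle exit with wall
#' absorption (radius > `inner_radius` terminates), aperture masking,
#' compensator degradation, and drift to `face_z` (the phantom entry face).
#'
#' @param states a [proton_states()] collection at the source plane.
#' @param source a [source_model()] (provides the source plane z and foil
#'   thickness).
#' @param nozzle a [nozzle_geometry()]; its `foil_thickness_mm` is overridden
#'   by the source's.
#' @param ap optional `pmc_aperture`.
#' @param comp optional `pmc_compensator`.
#' @param face_z phantom entry plane in cm (default 0, face at isocenter).
#' @param materials material table.
#' @param model a [range_energy_model()].
#' @return Collection at the phantom face; blocked/absorbed protons are dead.
#' @export
beamline_transport <- function(states, source, nozzle = nozzle_geometry(),
                               ap = NULL, comp = NULL, face_z = 0,
                               materials = pmc_materials(),
                               model = range_energy_model()) {
  src_z <- -source$source_to_isocenter
  foil_z <- (src_z + nozzle$exit_z) / 2
  states <- propagate_to_plane(states, foil_z)
  states <- traverse_foil(states, source$foil_thickness_mm, materials, model)
  states <- propagate_to_plane(states, nozzle$exit_z)
  wall <- states$alive &
    (states$x^2 + states$y^2 > nozzle$inner_radius^2)
  states$alive[wall] <- FALSE
  if (!is.null(ap)) {
    states <- propagate_to_plane(states, ap$z_position)
    states <- apply_aperture(states, ap)
  }
  if (!is.null(comp)) {
    states <- propagate_to_plane(states, comp$z_position)
    states <- apply_compensator(states, comp, model)
  }
  propagate_to_plane(states, face_z)
}

#' Write / read a compensator map as CSV with a small header
#'
#' The first lines hold `# pixel_size` and `# origin` comments followed by
#' the thickness matrix.
#'
#' @param comp a [compensator()].
#' @param path file path.
#' @export
write_compensator <- function(comp, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# pixel_size_cm: %g", comp$pixel_size),
               sprintf("# origin_cm: %g %g", comp$origin[1], comp$origin[2]),
               sprintf("# material: %s", comp$material$name)), con)
  utils::write.table(comp$thickness_map, con, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  close(con)
  invisible(path)
}

#' @rdname write_compensator
#' @param materials material table used to resolve the header's material.
#' @export
read_compensator <- function(path, materials = pmc_materials()) {
  hdr <- readLines(path, n = 3L)
  px <- as.numeric(sub("# pixel_size_cm: ", "", hdr[1]))
  org <- as.numeric(strsplit(sub("# origin_cm: ", "", hdr[2]), " ")[[1]])
  mat <- sub("# material: ", "", hdr[3])
  m <- as.matrix(utils::read.table(path, skip = 3L, sep = ","))
  dimnames(m) <- NULL
  compensator(m, px, org, materials[[mat]])
}
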