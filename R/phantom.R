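#' Voxelised phantom
#'
#' A rectangular voxel grid of materials with world placement. For homogeneous
#' phantoms (e.g. a water tank) `material_index` may be `NULL`, meaning every
#' voxel is the first (only) entry of `materials`; transport then skips the
#' per-voxel lookup entirely.
#'
#' The world frame has the beam travelling along +z with isocenter at the
#' origin; `origin` is the minimum corner of the grid.
#'
#' @param origin minimum corner `c(x, y, z)` in cm.
#' @param voxel voxel sizes `c(dx, dy, dz)` in cm, all > 0.
#' @param dims integer voxel counts `c(nx, ny, nz)`.
#' @param materials character vector of material names; every id used in
#'   `material_index` refers into this vector.
#' @param material_index optional integer array of dim `dims` with values in
#'   `1..length(materials)`.
#' @param density_override optional numeric array of dim `dims` with mass
#'   densities in g/cm^3 replacing the nominal material density (stopping
#'   power and scattering scale proportionally).
#' @return Object of class `pmc_phantom`.
#' @export
phantom <- function(origin, voxel, dims, materials = "water",
                    material_index = NULL, density_override = NULL) {
  stopifnot(length(origin) == 3L, length(voxel) == 3L, length(dims) == 3L)
  if (any(voxel <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  if (any(dims < 1)) stop("dims must be >= 1", call. = FALSE)
  dims <- as.integer(dims)
  if (!is.null(material_index)) {
    if (!identical(dim(material_index), dims))
      stop("material_index dim must equal dims", call. = FALSE)
    if (any(material_index < 1L | material_index > length(materials)))
      stop("material_index values must index into materials", call. = FALSE)
  }
  if (!is.null(density_override) && !identical(dim(density_override), dims))
    stop("density_override dim must equal dims", call. = FALSE)
  structure(list(origin = as.numeric(origin), voxel = as.numeric(voxel),
                 dims = dims, materials = materials,
                 material_index = material_index,
                 density_override = density_override),
            class = "pmc_phantom")
}

#' @export
print.pmc_phantom <- function(x, ...) {
  cat(sprintf("<pmc_phantom> %d x %d x %d voxels of %g x %g x %g cm; materials: %s\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel[1], x$voxel[2], x$voxel[3],
              paste(x$materials, collapse = ", ")))
  invisible(x)
}

#' Scoring mesh / dose grid constructor
#'
#' Allocates an empty energy-deposit mesh. The mesh may differ from the
#' phantom grid (e.g. 1 mm axial scoring with coarser lateral bins).
#' `deposit` accumulates weighted energy deposits (MeV); `deposit_sq`
#' accumulates the squared per-batch deposits used for the statistical
#' uncertainty estimate.
#'
#' @inheritParams phantom
#' @return Object of class `pmc_dose_grid`.
#' @export
dose_grid <- function(origin, voxel, dims) {
  stopifnot(length(origin) == 3L, length(voxel) == 3L, length(dims) == 3L)
  if (any(voxel <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  dims <- as.integer(dims)
  structure(list(origin = as.numeric(origin), voxel = as.numeric(voxel),
                 dims = dims,
                 deposit = array(0, dims), deposit_sq = array(0, dims),
                 histories = 0L, n_batches = 0L,
                 launched_energy = 0, deposited_energy = 0,
                 escaped_energy = 0, n_escaped = 0L,
                 provenance = list()),
            class = "pmc_dose_grid")
}

#' @export
print.pmc_dose_grid <- function(x, ...) {
  cat(sprintf(paste0("<pmc_dose_grid> %d x %d x %d voxels; %d histories in ",
                     "%d batches; %.4g MeV deposited\n"),
              x$dims[1], x$dims[2], x$dims[3], x$histories, x$n_batches,
              x$deposited_energy))
  invisible(x)
}

#' Voxel-centre axes of a dose grid or phantom
#' @param g a `pmc_dose_grid` or `pmc_phantom`.
#' @return list with numeric vectors `x`, `y`, `z` of voxel centres (cm).
#' @export
dose_grid_axes <- function(g) {
  list(x = g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$voxel[1],
       y = g$origin[2] + (seq_len(g$dims[2]) - 0.5) * g$voxel[2],
       z = g$origin[3] + (seq_len(g$dims[3]) - 0.5) * g$voxel[3])
}

#' Write / read a dose grid as text (JSON header + sparse CSV payload)
#'
#' `path` is the JSON header; voxel data go to `<path>.csv` as sparse
#' `(i, j, k, deposit, deposit_sq)` rows (1-based indices). Self-describing
#' and diff-able; no binary formats.
#'
#' @param dose a `pmc_dose_grid`.
#' @param path output path for the JSON header.
#' @export
write_dose_grid <- function(dose, path) {
  stopifnot(inherits(dose, "pmc_dose_grid"))
  nz <- which(dose$deposit != 0 | dose$deposit_sq != 0, arr.ind = TRUE)
  payload <- paste0(path, ".csv")
  df <- data.frame(i = nz[, 1], j = nz[, 2], k = nz[, 3],
                   deposit = dose$deposit[nz],
                   deposit_sq = dose$deposit_sq[nz])
  utils::write.csv(df, payload, row.names = FALSE)
  meta <- dose[c("origin", "voxel", "dims", "histories", "n_batches",
                 "launched_energy", "deposited_energy", "escaped_energy",
                 "n_escaped", "provenance")]
  meta$payload <- basename(payload)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- dose_grid(meta$origin, meta$voxel, meta$dims)
  df <- utils::read.csv(file.path(dirname(path), meta$payload))
  idx <- cbind(df$i, df$j, df$k)
  g$deposit[idx] <- df$deposit
  g$deposit_sq[idx] <- df$deposit_sq
  g$histories <- as.integer(meta$histories)
  g$n_batches <- as.integer(meta$n_batches)
  g$launched_energy <- meta$launched_energy
  g$deposited_energy <- meta$deposited_energy
  g$escaped_energy <- meta$escaped_energy
  g$n_escaped <- as.integer(meta$n_escaped)
  g$provenance <- as.list(meta$provenance)
  g
}
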