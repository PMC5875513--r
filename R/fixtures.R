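#' Homogeneous water tank phantom
#'
#' The commissioning geometry: a cubic block of liquid water with its entry
#' face at `face_z` (default at isocenter). Stored as a uniform phantom, so
#' no voxel grid is allocated; `voxel_mm` only fixes the default scoring
#' resolution of meshes derived from it.
#'
#' @param side cube side in cm (default 40).
#' @param voxel_mm voxel size in mm (default 1).
#' @param face_z z of the upstream face in cm (default 0).
#' @return A [phantom()] of water.
#' @examples
#' tank <- make_water_tank()
#' prod(tank$dims) # 400^3 voxels at 1 mm
#' @export
make_water_tank <- function(side = 40, voxel_mm = 1, face_z = 0) {
  v <- voxel_mm / 10
  n <- round(side / v)
  phantom(origin = c(-side / 2, -side / 2, face_z),
          voxel = c(v, v, v), dims = c(n, n, n), materials = "water")
}

#' Stair-shaped Lucite compensator
#'
#' Three parallel Lucite steps with sharp edges, each 6 cm wide (along x),
#' 2.7, 0.2 and 5.2 cm thick, covering an 18 x 18 cm field; the step edges
#' sit at x = -3 and x = +3 cm. Used with a circular aperture of radius
#' 6.5 cm and a range 15.2 / modulation 10.0 beam it reproduces the sharp
#' lateral heterogeneity benchmark.
#'
#' @param pixel_size map pixel in cm (default 0.5).
#' @param z_position compensator plane in cm (default -38).
#' @param material compensator material (default Lucite).
#' @return A [compensator()].
#' @examples
#' comp <- make_stair_compensator()
#' compensator_thickness(comp, c(-6, 0, 6), c(0, 0, 0)) # 2.7 0.2 5.2
#' @export
make_stair_compensator <- function(pixel_size = 0.5, z_position = -38,
                                   material = pmc_materials()$lucite) {
  nx <- round(18 / pixel_size)
  xc <- -9 + (seq_len(nx) - 0.5) * pixel_size
  col <- ifelse(xc < -3, 2.7, ifelse(xc < 3, 0.2, 5.2))
  m <- matrix(rep(col, nx), nrow = nx, ncol = nx)
  compensator(m, pixel_size, origin = c(-9, -9), material = material,
              z_position = z_position)
}

#' Heterogeneous bone/lung slab phantom
#'
#' A solid-water block with adjacent bone and lung slabs placed side by side
#' at depth: bone occupies x < 0 and lung x >= 0 over the slab's depth
#' interval, with a sharp axis-parallel interface at x = 0. Slab thickness
#' and depth are configurable; the defaults (2 cm slabs at 4 cm depth) are
#' generic since only qualitative behaviour (range pulled back behind bone,
#' pushed forward behind lung) is asserted. The companion field used with it
#' is a 5 x 7 cm rectangular aperture and no compensator, attached as
#' `attr(, "aperture")`.
#'
#' @param side lateral extent in cm (default 16).
#' @param depth phantom depth in cm (default 20).
#' @param slab_depth upstream face of the slabs in cm (default 4).
#' @param slab_thickness slab thickness in cm (default 2).
#' @param voxel_mm voxel size in mm (default 2).
#' @param face_z z of the upstream face in cm (default 0).
#' @return A [phantom()] with materials solid_water / bone / lung.
#' @export
make_slab_phantom <- function(side = 16, depth = 20, slab_depth = 4,
                              slab_thickness = 2, voxel_mm = 2, face_z = 0) {
  v <- voxel_mm / 10
  nx <- round(side / v); nz <- round(depth / v)
  idx <- array(1L, dim = c(nx, nx, nz))
  xc <- -side / 2 + (seq_len(nx) - 0.5) * v
  zc <- face_z + (seq_len(nz) - 0.5) * v
  in_slab <- zc >= face_z + slab_depth &
    zc < face_z + slab_depth + slab_thickness
  idx[xc < 0, , in_slab] <- 2L
  idx[xc >= 0, , in_slab] <- 3L
  ph <- phantom(origin = c(-side / 2, -side / 2, face_z),
                voxel = c(v, v, v), dims = c(nx, nx, nz),
                materials = c("solid_water", "bone", "lung"),
                material_index = idx)
  attr(ph, "aperture") <- aperture_rectangle(5, 7)
  ph
}
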