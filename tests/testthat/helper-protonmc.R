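# Shared helpers: small geometries and quick pencil-beam runs so individual
# tests stay fast. Everything is generated in code; no stored fixtures.

small_water_phantom <- function(depth = 9.5, half = 5, voxel = c(0.25, 0.25, 0.1)) {
  phantom(origin = c(-half, -half, 0), voxel = voxel,
          dims = c(round(2 * half / voxel[1]), round(2 * half / voxel[2]),
                   round(depth / voxel[3])))
}

pencil_states <- function(n, energy, sigma = 0) {
  e <- if (sigma > 0) stats::rnorm(n, energy, sigma) else rep(energy, n)
  proton_states(x = rep(0, n), y = rep(0, n), z = rep(0, n),
                ux = rep(0, n), uy = rep(0, n), uz = rep(1, n),
                energy = pmax(e, 1))
}

run_pencil <- function(n, energy, sigma = 0, seed = 42, depth = 9.5,
                       phantom_obj = NULL) {
  set.seed(seed)
  st <- pencil_states(n, energy, sigma)
  ph <- if (is.null(phantom_obj)) small_water_phantom(depth) else phantom_obj
  transport_in_phantom(st, ph)
}

# cache expensive shared objects across tests within one run
.pmc_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .pmc_cache)) assign(key, expr, envir = .pmc_cache)
  get(key, envir = .pmc_cache)
}
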