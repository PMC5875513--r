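test_that("highland_sigma matches the formula and its limits", {
  # 100 MeV, x/X0 = 0.01: pv ~ 190.4 MeV, bracket 0.778 -> ~5.8 mrad
  expect_equal(highland_sigma(100, 0.01 * 36.08, 36.08), 0.0058,
               tolerance = 0.01)
  expect_identical(highland_sigma(100, 0, 36.08), 0)
  x <- seq(0.1, 5, 0.1)
  s <- highland_sigma(100, x, 36.08)
  expect_true(all(diff(s) > 0))  # strictly increasing in path length
  expect_error(highland_sigma(-5, 1, 36.08), "energy")
})

test_that("step_length respects all three caps and the boundary clamp", {
  pol <- step_policy(max_step_cm = 0.1, range_fraction = 0.2)
  ph <- small_water_phantom()
  # residual range 0.05 cm -> step <= 0.01 (range-fraction bound)
  e_small <- energy_from_range(0.05)
  st <- proton_states(0.125, 0.125, 5.05, 0, 0, 1, e_small)
  expect_lte(step_length(st, ph, pol)[1], 0.011)
  # mid-voxel far from any lateral boundary: max_step rules
  st2 <- proton_states(0.125, 0.125, 5.05, 0, 0, 1, 150)
  expect_equal(step_length(st2, ph, pol)[1], 0.1)
  # heterogeneous phantom: the step stops at the voxel boundary
  idx <- array(1L, dim = c(4, 4, 4))
  idx[, , 3:4] <- 2L
  ph2 <- phantom(c(-2, -2, 0), c(1, 1, 1), c(4, 4, 4),
                 materials = c("water", "bone"), material_index = idx)
  st3 <- proton_states(0.5, 0.5, 1.7, 0, 0, 1, 150)
  s <- step_length(st3, ph2, step_policy(max_step_cm = 2))
  expect_lte(s[1], 0.3 + 1e-6)  # clamped at z = 2 plane
})

test_that("energy bookkeeping closes exactly and dose is conserved", {
  dg <- run_pencil(2000, 102.7, sigma = 0.8, seed = 9)
  expect_equal(dg$deposited_energy + dg$escaped_energy, dg$launched_energy,
               tolerance = 1e-9)
  expect_lte(dg$deposited_energy, dg$launched_energy)
  expect_true(all(dg$deposit >= 0))
  # scored mesh total cannot exceed the deposited total
  expect_lte(sum(dg$deposit), dg$deposited_energy + 1e-9)
})

test_that("monoenergetic 102.7 MeV pencil peaks at 7.8-8.0 cm depth", {
  dg <- cached("mono_pencil", run_pencil(8000, 102.7, seed = 42))
  dd <- depth_dose(dg, box = c(Inf, Inf))
  peak <- dd$coordinate[which.max(dd$value)]
  expect_gte(peak, 7.8)
  expect_lte(peak, 8.0)
  # distal r90 within 1 mm of the model range
  expect_equal(distal_metrics(dd)$r90, range_from_energy(102.7),
               tolerance = 0.1)
})

test_that("lateral dose is symmetric for a symmetric beam", {
  dg <- cached("mono_pencil", run_pencil(8000, 102.7, seed = 42))
  prof <- lateral_profile(dg, depth_cm = 4)
  x <- prof$coordinate; v <- prof$value
  sel <- abs(x) <= 1.5 & abs(x) > 0.1
  left <- v[sel & x < 0]; right <- rev(v[sel & x > 0])
  # first moment of the deposit about the axis ~ 0 within statistics
  g <- dose_grid_axes(dg)
  wsum <- apply(dg$deposit, 1, sum)
  mx <- sum(g$x * wsum) / sum(wsum)
  expect_lt(abs(mx), 3 * 0.5 / sqrt(8000))
  expect_equal(mean(left - right), 0, tolerance = 3 * sd(left) / sqrt(length(left)) + 0.05)
})

test_that("distal falloff widens monotonically with source energy sigma", {
  f <- vapply(c(0.3, 1.0, 2.5), function(sg) {
    dd <- depth_dose(run_pencil(6000, 100, sigma = sg, seed = 11),
                     box = c(Inf, Inf))
    distal_metrics(dd)$distal_falloff_80_20
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("estimate_uncertainty reproduces the hand-computed SEM", {
  # one voxel, three histories depositing 1, 1, 2 MeV (one batch each):
  # SEM/mean = (0.333)/1.333 = 0.25
  g <- dose_grid(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1))
  g$deposit[1] <- 4
  g$deposit_sq[1] <- 1 + 1 + 4
  g$histories <- 3L
  g$n_batches <- 3L
  u <- estimate_uncertainty(g)
  expect_equal(u$region, 0.25, tolerance = 1e-9)
  # identical deposits every history -> zero uncertainty
  g2 <- g
  g2$deposit[1] <- 3
  g2$deposit_sq[1] <- 3
  expect_equal(estimate_uncertainty(g2)$region, 0, tolerance = 1e-12)
  g3 <- g; g3$n_batches <- 1L
  expect_error(estimate_uncertainty(g3), "batches")
})

test_that("region uncertainty scales as 1/sqrt(N) within 20%", {
  # averaged over seeds: the batch estimator itself carries ~10% noise
  u1 <- mean(vapply(21:23, function(s)
    estimate_uncertainty(run_pencil(3000, 100, seed = s))$region, numeric(1)))
  u4 <- mean(vapply(31:33, function(s)
    estimate_uncertainty(run_pencil(12000, 100, seed = s))$region, numeric(1)))
  expect_equal(u1 / u4, 2, tolerance = 0.2)
})

test_that("transport is bit-for-bit reproducible for a fixed seed", {
  a <- run_pencil(600, 90, sigma = 1, seed = 33)
  b <- run_pencil(600, 90, sigma = 1, seed = 33)
  expect_identical(a$deposit, b$deposit)
  expect_identical(a$deposit_sq, b$deposit_sq)
  expect_identical(a$escaped_energy, b$escaped_energy)
})

test_that("protons exiting the grid are counted as escaped", {
  # beam aimed sideways exits quickly; everything not deposited escapes
  n <- 200
  st <- proton_states(rep(0, n), rep(0, n), rep(0.05, n),
                      rep(1, n), rep(0, n), rep(0, n), rep(100, n))
  ph <- small_water_phantom(depth = 1, half = 0.5)
  dg <- transport_in_phantom(st, ph, seed = 1)
  expect_gt(dg$n_escaped, 0)
  expect_equal(dg$deposited_energy + dg$escaped_energy, dg$launched_energy,
               tolerance = 1e-9)
})

test_that("proton_states validates invariants", {
  expect_error(proton_states(0, 0, 0, 0.5, 0, 0.5, 100), "unit")
  expect_error(proton_states(0, 0, 0, 0, 0, 1, -5), "energy")
  expect_error(proton_states(0, 0, 0, 0, 0, 1, 5, weight = 0), "weight")
})

test_that("density override rescales stopping and scattering", {
  # doubling water density via override halves the physical range
  ov <- array(2, dim = c(8, 8, 60))
  ph <- phantom(c(-2, -2, 0), c(0.5, 0.5, 0.1), c(8, 8, 60),
                materials = "water", density_override = ov)
  dd <- depth_dose(run_pencil(1500, 102.7, seed = 13, phantom_obj = ph),
                   box = c(Inf, Inf))
  expect_equal(distal_metrics(dd)$r90, 4.0, tolerance = 0.1)
})
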