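test_that("curve1d validates and normalises", {
  expect_error(curve1d(1, 1), "points")
  expect_error(curve1d(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(curve1d(1:3, 1:2), "lengths")
  cv <- curve1d(1:5, c(1, 2, 5, 2, 1), normalize = TRUE)
  expect_equal(max(cv$value), 100)
})

test_that("depth_dose extracts and normalises a synthetic grid exactly", {
  g <- dose_grid(c(-2, -2, 0), c(0.5, 0.5, 0.1), c(8, 8, 50))
  ax <- dose_grid_axes(g)
  prof <- ifelse(ax$z - ax$z[1] + 0.05 < 4, 50, 0)  # step profile, known values
  for (k in seq_len(50)) g$deposit[, , k] <- prof[k]
  dd <- depth_dose(g, box = c(Inf, Inf))
  expect_equal(dd$value[dd$coordinate < 4], rep(100, sum(dd$coordinate < 4)))
  expect_equal(dd$coordinate, seq(0.05, 4.95, 0.1))
  dd2 <- depth_dose(g, box = c(0.5, 0.5), normalize = "none")
  expect_equal(dd2$value[1], 50)
  expect_error(depth_dose(g, box = c(0.5, 0.5), center = c(50, 0)), "outside")
})

test_that("lateral_profile normalises to the central axis and validates depth", {
  g <- dose_grid(c(-2, -2, 0), c(0.25, 0.25, 0.5), c(16, 16, 10))
  ax <- dose_grid_axes(g)
  vals <- outer(exp(-ax$x^2), exp(-ax$y^2 / 4))
  for (k in 1:10) g$deposit[, , k] <- vals * k
  pr <- lateral_profile(g, depth_cm = 2.2)
  expect_equal(max(pr$value), 100, tolerance = 1e-9)
  expect_equal(pr$value,
               100 * exp(-ax$x^2) / exp(-ax$x[9]^2), tolerance = 1e-9)
  expect_error(lateral_profile(g, depth_cm = 9), "depth")
})

test_that("distal_metrics interpolates thresholds on a linear ramp", {
  # ramp 100 -> 0 over [10, 11]: r90 = 10.1, r80 = 10.2, r20 = 10.8
  z <- seq(0, 12, 0.05)
  d <- ifelse(z < 10, 100, pmax(0, 100 * (11 - z)))
  mt <- distal_metrics(curve1d(z, d))
  expect_equal(mt$r90, 10.1, tolerance = 1e-6)
  expect_equal(mt$r80, 10.2, tolerance = 1e-6)
  expect_equal(mt$r20, 10.8, tolerance = 1e-6)
  expect_equal(mt$distal_falloff_80_20, 0.6, tolerance = 1e-6)
  expect_true(mt$r90 <= mt$r80 && mt$r80 <= mt$r20)
  # flat curve with no falloff errors, naming the missing threshold
  expect_error(distal_metrics(curve1d(1:10, rep(100, 10))), "90")
})

test_that("ideal rectangular SOBP recovers its modulation as sampling -> 0", {
  for (h in c(0.05, 0.01)) {
    z <- seq(0, 10, h)
    d <- ifelse(z >= 3 & z <= 8, 100, 0)
    mt <- distal_metrics(curve1d(z, d))
    expect_equal(mt$modulation, 5, tolerance = 2 * h)
    expect_equal(mt$flatness, 0)
  }
})

test_that("threshold crossings are stable under sampling refinement", {
  f <- function(z) 100 / (1 + exp((z - 9) / 0.15))
  for (h in c(0.2, 0.1)) {
    z <- seq(0, 11, h)
    mt <- distal_metrics(curve1d(z, f(z)))
    zf <- seq(0, 11, h / 2)
    mtf <- distal_metrics(curve1d(zf, f(zf)))
    expect_lt(abs(mt$r90 - mtf$r90), h)
    expect_lt(abs(mt$r20 - mtf$r20), h)
  }
})

test_that("penumbra_80_20 matches the Gaussian quantile spacing", {
  x <- seq(-6, 6, 0.01)
  for (s in c(0.3, 0.8)) {
    edge <- 100 * pnorm((2 - abs(x)) / s)  # field of half-width 2, blur s
    p <- penumbra_80_20(curve1d(x, edge))
    expect_equal(unname(p["left"]), 1.683 * s, tolerance = 0.02)
    expect_equal(unname(p["right"]), 1.683 * s, tolerance = 0.02)
    expect_equal(unname(p["left"] - p["right"]), 0, tolerance = 1e-9)
  }
  # perfect step: penumbra collapses with sampling
  xs <- seq(-3, 3, 0.001)
  step <- ifelse(abs(xs) <= 1.5, 100, 0)
  p <- penumbra_80_20(curve1d(xs, step))
  expect_lt(max(p), 0.002)
  expect_error(penumbra_80_20(curve1d(xs, rep(100, length(xs)))), "shoulder")
})

test_that("penumbra and falloff are invariant under uniform dose rescaling", {
  x <- seq(-6, 6, 0.01)
  edge <- 37.5 * pnorm((2 - abs(x)) / 0.5)
  expect_equal(penumbra_80_20(curve1d(x, edge)),
               penumbra_80_20(curve1d(x, 4.2 * edge)))
  z <- seq(0, 12, 0.05)
  d <- ifelse(z < 10, 80, pmax(0, 80 * (11 - z)))
  expect_equal(distal_metrics(curve1d(z, d))$distal_falloff_80_20,
               distal_metrics(curve1d(z, 0.01 * d))$distal_falloff_80_20)
})

test_that("gamma_pass_rate obeys its identity and tolerance contracts", {
  z <- seq(0, 10, 0.1)
  d <- 100 * exp(-(z - 5)^2 / 8)
  ref <- curve1d(z, d)
  expect_equal(gamma_pass_rate(ref, ref), 100)
  # uniform +1.9% scaling stays inside the 2% dose tolerance
  expect_equal(gamma_pass_rate(ref, curve1d(z, 1.019 * d)), 100)
  # +5% on a perfectly flat region: no gradient, no DTA rescue
  flat <- curve1d(z, rep(50, length(z)))
  expect_equal(gamma_pass_rate(flat, curve1d(z, rep(52.5, length(z)))), 0)
  # low-dose threshold excludes the tails
  expect_error(gamma_pass_rate(curve1d(z, rep(1, length(z))),
                               curve1d(z, rep(1, length(z))),
                               threshold = 200), "threshold")
  expect_error(gamma_pass_rate(ref, curve1d(z + 100, d)), "overlap")
})

test_that("gamma identity holds for dose grids and DTA rescues shifts", {
  g <- dose_grid(c(-2, -2, 0), c(0.2, 0.2, 0.2), c(20, 20, 20))
  ax <- dose_grid_axes(g)
  for (k in 1:20) g$deposit[, , k] <- 50 * exp(-(ax$z[k] - 2)^2) *
    outer(exp(-ax$x^2), exp(-ax$y^2))
  expect_equal(gamma_pass_rate(g, g), 100)
  # one-voxel axial shift (2 mm) is within the DTA
  g2 <- g
  g2$deposit <- g$deposit[, , c(1, 1:19)]
  expect_gt(gamma_pass_rate(g, g2), 99)
  g3 <- g; g3$voxel <- c(0.3, 0.3, 0.3)
  expect_error(gamma_pass_rate(g, g3), "geometry")
})

test_that("curves round-trip through CSV", {
  cv <- curve1d(seq(0, 5, 0.5), sin(seq(0, 5, 0.5)) + 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, tmp)
  expect_equal(read_curve(tmp), cv)
})
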