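#' One-dimensional dose curve
#'
#' Container for an extracted depth-dose or lateral profile: a strictly
#' increasing coordinate (cm) and a dose value per point.
#'
#' @param coordinate positions in cm, strictly increasing, length >= 2.
#' @param value dose values (relative units), same length.
#' @param normalize if `TRUE`, rescale so that max(value) = 100.
#' @return Object of class `pmc_curve1d` (a list with `coordinate`, `value`).
#' @export
curve1d <- function(coordinate, value, normalize = FALSE) {
  if (length(coordinate) < 2L) stop("curve needs >= 2 points", call. = FALSE)
  if (length(coordinate) != length(value))
    stop("coordinate and value lengths differ", call. = FALSE)
  if (any(diff(coordinate) <= 0))
    stop("coordinate must be strictly increasing", call. = FALSE)
  if (normalize) value <- 100 * value / max(value)
  structure(list(coordinate = as.numeric(coordinate),
                 value = as.numeric(value)),
            class = "pmc_curve1d")
}

#' @export
print.pmc_curve1d <- function(x, ...) {
  cat(sprintf("<pmc_curve1d> %d points over [%.3g, %.3g] cm, max %.4g\n",
              length(x$coordinate), min(x$coordinate), max(x$coordinate),
              max(x$value)))
  invisible(x)
}

#' Write / read a curve as two-column CSV
#' @param curve a [curve1d()].
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "pmc_curve1d"))
  utils::write.csv(data.frame(coordinate_cm = curve$coordinate,
                              dose = curve$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  curve1d(df[[1]], df[[2]])
}

# Normalise a depth-dose curve so the plateau mean (points within 5% of the
# near-maximum) is 100. For a pristine peak the "plateau" collapses to the
# peak region, so the same rule gives peak ~= 100.
.normalize_plateau <- function(curve) {
  m <- stats::quantile(curve$value, 0.98, names = FALSE)
  ref <- mean(curve$value[curve$value >= 0.95 * m])
  curve1d(curve$coordinate, 100 * curve$value / ref)
}

#' Extract a laterally averaged depth-dose curve
#'
#' Averages the dose over a lateral box centred on `center` at every depth of
#' the scoring grid and normalises so the plateau mean (SOBP) or peak
#' (pristine beam) is 100. Depth is measured along +z from the grid origin.
#'
#' @param dose a `pmc_dose_grid` (see [transport_in_phantom()]).
#' @param box lateral half-widths `c(hx, hy)` in cm of the averaging region;
#'   default `c(0.5, 0.5)` (a 1 x 1 cm box, a chamber-footprint surrogate).
#'   Use `Inf` to integrate the full grid.
#' @param center lateral centre `c(x, y)` in cm; default on axis.
#' @param normalize one of "plateau" (default; plateau mean or peak = 100) or
#'   "none".
#' @return A [curve1d()] of dose vs depth (cm from the grid's upstream face).
#' @export
depth_dose <- function(dose, box = c(0.5, 0.5), center = c(0, 0),
                       normalize = c("plateau", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(dose, "pmc_dose_grid"))
  g <- dose_grid_axes(dose)
  ix <- which(abs(g$x - center[1]) <= box[1] + 1e-9)
  iy <- which(abs(g$y - center[2]) <= box[2] + 1e-9)
  if (length(ix) == 0L || length(iy) == 0L)
    stop("lateral averaging box lies outside the scoring grid", call. = FALSE)
  prof <- apply(dose$deposit[ix, iy, , drop = FALSE], 3L, mean)
  cv <- curve1d(g$z - g$z[1] + dose$voxel[3] / 2, prof)
  if (normalize == "plateau") .normalize_plateau(cv) else cv
}

#' Extract a lateral dose profile at a given depth
#'
#' Dose vs off-axis position at depth `depth_cm` (from the grid's upstream
#' face), averaged over the orthogonal lateral direction within `ortho_half`
#' and over one depth bin, normalised to the central-axis value = 100.
#'
#' @inheritParams depth_dose
#' @param depth_cm depth in cm; must lie inside the grid.
#' @param direction "x" or "y".
#' @param ortho_half half-width in cm of averaging along the orthogonal
#'   lateral axis (default 0.5).
#' @return A [curve1d()] of dose vs off-axis position.
#' @export
lateral_profile <- function(dose, depth_cm, direction = c("x", "y"),
                            ortho_half = 0.5) {
  direction <- match.arg(direction)
  stopifnot(inherits(dose, "pmc_dose_grid"))
  g <- dose_grid_axes(dose)
  zq <- g$z[1] - dose$voxel[3] / 2 + depth_cm
  iz <- which.min(abs(g$z - zq))
  if (depth_cm < 0 || depth_cm > dose$dims[3] * dose$voxel[3])
    stop("depth outside the scoring grid", call. = FALSE)
  if (direction == "x") {
    io <- which(abs(g$y) <= ortho_half + 1e-9)
    prof <- apply(dose$deposit[, io, iz, drop = FALSE], 1L, mean)
    coord <- g$x
  } else {
    io <- which(abs(g$x) <= ortho_half + 1e-9)
    prof <- apply(dose$deposit[io, , iz, drop = FALSE], 2L, mean)
    coord <- g$y
  }
  i0 <- which.min(abs(coord))
  if (prof[i0] <= 0) stop("no dose on the central axis at this depth",
                          call. = FALSE)
  curve1d(coord, 100 * prof / prof[i0])
}

# first crossing of `level`, scanning the curve in index order given by `idx`;
# linear interpolation between the bracketing samples
.cross <- function(x, y, level, from_distal = TRUE) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  idx <- if (from_distal) n:2 else 1:(n - 1)
  for (i in idx) {
    j <- if (from_distal) i - 1L else i + 1L
    lo <- y[i]; hi <- y[j]
    if ((lo < level && hi >= level) || (lo <= level && hi > level)) {
      t <- (level - lo) / (hi - lo)
      return(x[i] + t * (x[j] - x[i]))
    }
  }
  NA_real_
}

#' SOBP / pristine-peak depth-dose metrics
#'
#' Computes the clinical summary of a depth-dose curve: interpolated distal
#' 90/80/20% crossings, distal 80-20 falloff, proximal 90% crossing,
#' modulation (distal r90 - proximal r90) and plateau flatness (half the
#' peak-to-peak excursion over the plateau, relative to the plateau mean).
#' The curve is first rescaled so its plateau mean is 100, making the metrics
#' invariant under uniform dose rescaling.
#'
#' @param curve a [curve1d()] depth-dose with a distal falloff.
#' @param plateau_margin margin in cm excluded at both plateau ends when
#'   evaluating flatness (default 0.5).
#' @param smooth_cm optional moving-average window (cm) applied before the
#'   flatness evaluation only, to suppress per-bin Monte Carlo noise
#'   (default 0 = none).
#' @return Object of class `pmc_sobp_metrics`: list with `r90`, `r80`, `r20`,
#'   `distal_falloff_80_20`, `proximal_r90`, `modulation`, `flatness`.
#' @examples
#' z <- seq(0, 12, 0.05)
#' d <- ifelse(z < 10, 100, pmax(0, 100 * (11 - z)))
#' m <- distal_metrics(curve1d(z, d))
#' m$r90; m$distal_falloff_80_20
#' @export
distal_metrics <- function(curve, plateau_margin = 0.5, smooth_cm = 0) {
  stopifnot(inherits(curve, "pmc_curve1d"))
  curve <- .normalize_plateau(curve)
  x <- curve$coordinate; y <- curve$value
  r90 <- .cross(x, y, 90, from_distal = TRUE)
  r80 <- .cross(x, y, 80, from_distal = TRUE)
  r20 <- .cross(x, y, 20, from_distal = TRUE)
  for (nm in c("r90", "r80", "r20"))
    if (is.na(get(nm)))
      stop("distal ", sub("r", "", nm), "% level never crossed", call. = FALSE)
  p90 <- .cross(x, y, 90, from_distal = FALSE)
  if (is.na(p90)) p90 <- x[1]  # dose already above 90% at the first sample

  # flatness is judged on the true plateau: at large modulation-to-range
  # ratios the proximal 90->100% ramp is physically wide, so the plateau
  # start is taken at the proximal 98% crossing, not at p90
  p98 <- .cross(x, y, 98, from_distal = FALSE)
  if (is.na(p98)) p98 <- p90
  lo <- max(p90, p98) + plateau_margin; hi <- r90 - plateau_margin
  flat <- NA_real_
  sel <- x >= lo & x <= hi
  if (sum(sel) >= 2L) {
    yy <- y
    if (smooth_cm > 0) {
      k <- max(1L, round(smooth_cm / mean(diff(x))))
      if (k > 1L) yy <- stats::filter(y, rep(1 / k, k), sides = 2)
    }
    pv <- yy[sel & !is.na(yy)]
    flat <- 100 * (max(pv) - min(pv)) / 2 / mean(pv)
  }
  structure(list(r90 = r90, r80 = r80, r20 = r20,
                 distal_falloff_80_20 = r20 - r80,
                 proximal_r90 = p90,
                 modulation = r90 - p90,
                 flatness = flat),
            class = "pmc_sobp_metrics")
}

#' @export
print.pmc_sobp_metrics <- function(x, ...) {
  cat(sprintf(paste0("<pmc_sobp_metrics> r90 %.3f cm | modulation %.3f cm | ",
                     "distal 80-20 %.3f cm | flatness %.2f%%\n"),
              x$r90, x$modulation, x$distal_falloff_80_20, x$flatness))
  invisible(x)
}

#' Lateral 80-20 penumbra widths
#'
#' Interpolated distance between the 80% and 20% dose levels on each shoulder
#' of a lateral profile. The profile is normalised to its maximum = 100 first,
#' so the result is invariant under uniform rescaling.
#'
#' @param profile a [curve1d()] lateral profile crossing 80% and 20% on both
#'   shoulders.
#' @return Named numeric `c(left =, right =)` in cm.
#' @export
penumbra_80_20 <- function(profile) {
  stopifnot(inherits(profile, "pmc_curve1d"))
  x <- profile$coordinate
  y <- 100 * profile$value / max(profile$value)
  ipk <- which.max(y)
  xl <- x[1:ipk]; yl <- y[1:ipk]
  xr <- x[ipk:length(x)]; yr <- y[ipk:length(x)]
  l80 <- .cross(xl, yl, 80, from_distal = FALSE)
  l20 <- .cross(xl, yl, 20, from_distal = FALSE)
  r80 <- .cross(xr, yr, 80, from_distal = TRUE)
  r20 <- .cross(xr, yr, 20, from_distal = TRUE)
  if (any(is.na(c(l80, l20, r80, r20))))
    stop("profile does not cross both 80% and 20% on both shoulders",
         call. = FALSE)
  c(left = abs(l80 - l20), right = abs(r20 - r80))
}

#' Gamma-index pass rate for two dose curves
#'
#' Global-normalisation gamma analysis: for every evaluated point above the
#' low-dose threshold, gamma is the minimum over the (finely resampled)
#' reference curve of `sqrt((dD / dose_tol)^2 + (dx / dta)^2)`, with the dose
#' tolerance taken as a percentage of the reference maximum. Returns the
#' percentage of points with gamma <= 1.
#'
#' @param reference,evaluated [curve1d()] objects on overlapping coordinates,
#'   or `pmc_dose_grid` objects on identical geometry (voxelwise gamma with a
#'   lateral/axial distance-to-agreement search).
#' @param dose_tol dose tolerance in percent of the reference maximum
#'   (default 2).
#' @param dta_mm distance-to-agreement in mm (default 2).
#' @param threshold low-dose cutoff in percent of the reference maximum;
#'   points below it are excluded (default 10).
#' @return Pass rate in percent.
#' @export
gamma_pass_rate <- function(reference, evaluated, dose_tol = 2, dta_mm = 2,
                            threshold = 10) {
  if (inherits(reference, "pmc_dose_grid"))
    return(.gamma_grid(reference, evaluated, dose_tol, dta_mm, threshold))
  stopifnot(inherits(reference, "pmc_curve1d"),
            inherits(evaluated, "pmc_curve1d"))
  dta <- dta_mm / 10
  lo <- max(min(reference$coordinate), min(evaluated$coordinate))
  hi <- min(max(reference$coordinate), max(evaluated$coordinate))
  if (lo >= hi) stop("curves do not overlap", call. = FALSE)

  xe <- evaluated$coordinate
  keep <- xe >= lo & xe <= hi
  xe <- xe[keep]; de <- evaluated$value[keep]
  dmax <- max(reference$value)
  dd_tol <- dose_tol / 100 * dmax

  xr <- seq(lo, hi, by = min(dta / 10, min(diff(reference$coordinate)) / 2))
  dr <- stats::approx(reference$coordinate, reference$value, xout = xr)$y

  ref_at_e <- stats::approx(reference$coordinate, reference$value, xout = xe)$y
  eval_pts <- which(ref_at_e >= threshold / 100 * dmax)
  if (length(eval_pts) == 0L) stop("no points above threshold", call. = FALSE)

  g <- vapply(eval_pts, function(i) {
    win <- abs(xr - xe[i]) <= 3 * dta
    min(sqrt(((de[i] - dr[win]) / dd_tol)^2 + ((xe[i] - xr[win]) / dta)^2))
  }, numeric(1))
  100 * mean(g <= 1 + 1e-12)
}

# voxelwise gamma for two grids on identical geometry; DTA search over integer
# voxel shifts within the dta radius
.gamma_grid <- function(reference, evaluated, dose_tol, dta_mm, threshold) {
  stopifnot(inherits(evaluated, "pmc_dose_grid"))
  if (!isTRUE(all.equal(reference$dims, evaluated$dims)) ||
      !isTRUE(all.equal(reference$voxel, evaluated$voxel)) ||
      !isTRUE(all.equal(reference$origin, evaluated$origin)))
    stop("dose grids must share identical geometry", call. = FALSE)
  dta <- dta_mm / 10
  ref <- reference$deposit; ev <- evaluated$deposit
  dmax <- max(ref)
  dd_tol <- dose_tol / 100 * dmax
  sh <- lapply(1:3, function(a) {
    m <- floor(dta / reference$voxel[a])
    (-m):m
  })
  shifts <- expand.grid(i = sh[[1]], j = sh[[2]], k = sh[[3]])
  dist <- sqrt((shifts$i * reference$voxel[1])^2 +
               (shifts$j * reference$voxel[2])^2 +
               (shifts$k * reference$voxel[3])^2)
  shifts <- shifts[dist <= dta, , drop = FALSE]
  dist <- dist[dist <= dta]
  dm <- dim(ref)
  g2 <- array(Inf, dm)
  for (s in seq_len(nrow(shifts))) {
    i <- shifts$i[s]; j <- shifts$j[s]; k <- shifts$k[s]
    src <- list(seq_len(dm[1]) + i, seq_len(dm[2]) + j, seq_len(dm[3]) + k)
    ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= dm[a])
    dst <- lapply(1:3, function(a) which(ok[[a]]))
    rs <- ref[src[[1]][dst[[1]]], src[[2]][dst[[2]]], src[[3]][dst[[3]]],
              drop = FALSE]
    cand <- ((ev[dst[[1]], dst[[2]], dst[[3]], drop = FALSE] - rs) / dd_tol)^2 +
      (dist[s] / dta)^2
    sub <- g2[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    g2[dst[[1]], dst[[2]], dst[[3]]] <- pmin(sub, cand)
  }
  sel <- ref >= threshold / 100 * dmax
  if (!any(sel)) stop("no voxels above threshold", call. = FALSE)
  100 * mean(g2[sel] <= 1 + 1e-12)
}
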