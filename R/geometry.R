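## Lattice measurements: helical axis fit, diameter, adjacent-dimer COM
## separations, interprotofilament lateral angle, and the rotation-per-dimer
## (dPHI) skew statistic fitted from segment phi series.

#' Least-squares helical (cylinder) axis fit
#'
#' Finds the axis line minimizing the variance of point-to-axis radial
#' distances, so measurements do not assume the lattice sits at the origin
#' and work on externally loaded, rigidly moved models. Initialized from
#' the principal components of the point cloud and refined numerically.
#'
#' @param points Numeric matrix (n x 3) of coordinates.
#' @return List with `origin` (point on the axis), `direction` (unit
#'   vector) and `radii` (per-point radial distances).
#' @export
fit_helical_axis <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("axis fit needs at least 3 points")
  ctr <- colMeans(points)
  pc <- eigen(stats::cov(points), symmetric = TRUE)$vectors

  radial_var <- function(origin, dir) {
    d <- sweep(points, 2, origin)
    along <- d %*% dir
    rad <- sqrt(pmax(rowSums(d^2) - along^2, 0))
    stats::var(rad)
  }
  ## pick the principal direction with the most cylinder-like residuals
  v0 <- pc[, which.min(vapply(1:3, function(i) radial_var(ctr, pc[, i]),
                              numeric(1)))]
  e <- pc[, order(abs(t(pc) %*% v0))[1:2], drop = FALSE]  # plane basis

  obj <- function(p) {
    origin <- ctr + e %*% p[1:2]
    dir <- v0 + e %*% p[3:4]
    dir <- dir / sqrt(sum(dir^2))
    radial_var(drop(origin), drop(dir))
  }
  opt <- stats::optim(c(0, 0, 0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  origin <- drop(ctr + e %*% opt$par[1:2])
  dir <- drop(v0 + e %*% opt$par[3:4]); dir <- dir / sqrt(sum(dir^2))
  if (dir[3] < 0) dir <- -dir
  d <- sweep(points, 2, origin)
  along <- drop(d %*% dir)
  rad <- sqrt(pmax(rowSums(d^2) - along^2, 0))
  list(origin = origin, direction = dir, radii = rad, along = along)
}

#' Measure microtubule diameter from dimer centres of mass
#'
#' Diameter is twice the mean radial distance of dimer COMs to the
#' least-squares helical axis. Per-protofilament radii are reported for the
#' asymmetry analysis (the CKK-induced inward shifts are not symmetric
#' around the microtubule). Absolute diameters depend on where the monomer
#' reference point sits; only differences between lattices measured the
#' same way are meaningful.
#'
#' @param lat An `mt_lattice`.
#' @param axis Optional pre-fitted axis (as returned by
#'   [fit_helical_axis()]); when comparing a perturbed lattice to its
#'   reference, measuring both about the reference's axis makes asymmetric
#'   per-protofilament shifts exactly recoverable (about its own fitted
#'   axis, a first-harmonic radial displacement is partly absorbed into an
#'   axis translation).
#' @return List with `diameter` (Angstrom), `per_pf_radii` (named by pf)
#'   and the fitted `axis`.
#' @export
measure_diameter <- function(lat, axis = NULL) {
  stopifnot(inherits(lat, "mt_lattice"))
  if (lat$spec$n_pf < 3) stop("axis fit undefined for fewer than 3 pfs")
  dc <- dimer_coms(lat)
  xyz <- as.matrix(dc[, c("x", "y", "z")])
  if (is.null(axis)) {
    ax <- fit_helical_axis(xyz)
    radii <- ax$radii
  } else {
    ax <- axis
    d <- sweep(xyz, 2, ax$origin)
    along <- drop(d %*% ax$direction)
    radii <- sqrt(pmax(rowSums(d^2) - along^2, 0))
  }
  per_pf <- c(tapply(radii, dc$pf, mean))
  list(diameter = 2 * mean(radii), per_pf_radii = per_pf, axis = ax)
}

#' Compare two lattices (diameter, separations, lateral angle)
#'
#' Reference-versus-test comparison mirroring the decorated-microtubule
#' analyses: diameter difference, per-junction adjacent-dimer COM
#' separation differences (B-lattice junctions only by default) and
#' lateral-angle difference. Both lattices are measured about the
#' *reference's* fitted helical axis, so injected per-protofilament radial
#' offsets are recovered exactly at zero noise.
#'
#' @param ref,test `mt_lattice` objects with identical topology.
#' @param exclude_seam Exclude the seam junction from the separation
#'   comparison (default TRUE).
#' @param align Superpose `test` onto `ref` over all dimer COMs first
#'   (default FALSE; lattices from the same generator already share a
#'   frame — use TRUE for externally loaded models).
#' @return List of class `lattice_comparison`: `diameter_diff`
#'   (reference - test), `per_pf_radius_diff` (test - reference, recovers
#'   injected offsets), `separation_diffs` (reference - test, per
#'   junction), `mean_sep_diff`, `sep_diff_sd`, `lateral_angle_diff`
#'   (reference - test).
#' @export
compare_lattices <- function(ref, test, exclude_seam = TRUE,
                             align = FALSE) {
  stopifnot(inherits(ref, "mt_lattice"), inherits(test, "mt_lattice"))
  if (ref$spec$n_pf != test$spec$n_pf)
    stop("lattices must share protofilament number")
  if (align) {
    fit <- superpose_rigid(as.matrix(dimer_coms(test)[, c("x", "y", "z")]),
                           as.matrix(dimer_coms(ref)[, c("x", "y", "z")]))
    test <- transform_lattice(test, fit$rotation, fit$translation)
  }
  mref <- measure_diameter(ref)
  mtest <- measure_diameter(test, axis = mref$axis)
  sref <- adjacent_dimer_separations(ref, exclude_seam = exclude_seam)
  stest <- adjacent_dimer_separations(test, exclude_seam = exclude_seam)
  sep_diff <- sref - stest
  structure(list(
    diameter_diff = mref$diameter - mtest$diameter,
    per_pf_radius_diff = mtest$per_pf_radii - mref$per_pf_radii,
    separation_diffs = sep_diff,
    mean_sep_diff = mean(sep_diff),
    sep_diff_sd = if (length(sep_diff) > 1) stats::sd(sep_diff) else NA_real_,
    lateral_angle_diff = lateral_angle(ref) - lateral_angle(test)
  ), class = "lattice_comparison")
}

#' @export
print.lattice_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Lattice comparison (reference - test):\n",
           "  diameter difference: %.3f A\n",
           "  adjacent-dimer COM separation: %.3f +/- %.3f A over %d junctions\n",
           "  lateral angle difference: %.3f deg\n"),
    x$diameter_diff, x$mean_sep_diff, x$sep_diff_sd,
    length(x$separation_diffs), x$lateral_angle_diff))
  invisible(x)
}

#' Centre-of-mass separations of laterally adjacent dimers
#'
#' Walks one complete lateral turn of N dimers (one dimer per
#' protofilament, taken in helical order at a common dimer level) and
#' returns the Euclidean COM distance for each lateral junction. The seam
#' junction is excluded by default since the reference measurement concerns
#' B-lattice dimer pairs only.
#'
#' @param lat An `mt_lattice`.
#' @param exclude_seam Drop the seam junction (default TRUE; N-1 values).
#' @param ring Dimer level defining the turn (default: middle level).
#' @return Named numeric vector of separations in Angstrom, one per
#'   junction.
#' @export
adjacent_dimer_separations <- function(lat, exclude_seam = TRUE,
                                       ring = NULL) {
  stopifnot(inherits(lat, "mt_lattice"))
  N <- lat$spec$n_pf
  ring <- ring %||% (lat$spec$n_dimers %/% 2)
  dc <- dimer_coms(lat)
  dc <- dc[order(dc$m), ]
  ringd <- dc[dc$dimer == ring, ]
  if (nrow(ringd) != N) stop("incomplete dimer ring at level ", ring)
  xyz <- as.matrix(ringd[, c("x", "y", "z")])
  sep <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                         xyz[-N, , drop = FALSE])^2))
  names(sep) <- paste0(ringd$pf[-N], "-", ringd$pf[-1])
  if (!exclude_seam) {
    ## wrap (seam) junction: nearest dimer COM on the first pf of the turn
    last <- xyz[N, ]
    cand <- dc[dc$m == 0, ]
    dists <- sqrt(rowSums(sweep(as.matrix(cand[, c("x", "y", "z")]),
                                2, last)^2))
    sep <- c(sep, structure(min(dists),
                            names = paste0(ringd$pf[N], "-",
                                           cand$pf[1], "(seam)")))
  }
  sep
}

## Per-protofilament azimuth about the fitted axis, evaluated at a common
## axial position by a linear fit of unwrapped azimuth against z.
pf_azimuths_at <- function(lat, z_ref = NULL) {
  dc <- dimer_coms(lat)
  ax <- fit_helical_axis(as.matrix(dc[, c("x", "y", "z")]))
  dir <- ax$direction
  ## orthonormal basis perpendicular to the axis
  e1 <- c(dir[2], -dir[1], 0)
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  d <- sweep(as.matrix(dc[, c("x", "y", "z")]), 2, ax$origin)
  az <- atan2(d %*% e2, d %*% e1) * 180 / pi
  along <- d %*% dir
  z_ref <- z_ref %||% mean(along)
  vapply(split(seq_len(nrow(dc)), dc$pf), function(i) {
    phi <- unwrap_series(az[i][order(along[i])])
    zz <- sort(along[i])
    if (length(i) > 1 && stats::sd(zz) > 0) {
      fit <- stats::lm(phi ~ zz)
      unname(stats::predict(fit, data.frame(zz = z_ref)))
    } else phi[1]
  }, numeric(1))
}

#' Interprotofilament lateral angle
#'
#' Mean angle subtended at the helical axis between adjacent protofilament
#' centre lines, each evaluated at a common axial level. For an ideal
#' N-protofilament lattice this is 360/N degrees; the 13- versus
#' 14-protofilament difference of ~2 degrees is what makes higher-pf
#' architectures "shallower" at the CKK binding site.
#'
#' @param lat An `mt_lattice`.
#' @return Mean lateral angle in degrees.
#' @export
lateral_angle <- function(lat) {
  stopifnot(inherits(lat, "mt_lattice"))
  if (lat$spec$n_pf < 3) stop("lateral angle undefined for < 3 pfs")
  azs <- pf_azimuths_at(lat)
  azs <- sort(wrap_angle(azs, 360, center = 180))
  gaps <- diff(c(azs, azs[1] + 360))
  mean(gaps)
}

#' Compare lateral angles of two lattices
#'
#' @param latA,latB `mt_lattice` objects; each lattice's angle is measured
#'   about its own fitted axis, so no pre-alignment is required.
#' @return `lateral_angle(latA) - lateral_angle(latB)` in degrees.
#' @export
compare_lateral_angle <- function(latA, latB) {
  lateral_angle(latA) - lateral_angle(latB)
}

#' Measure the rotation-per-dimer skew of a lattice
#'
#' Fits each protofilament's dimer-COM azimuth (about the z axis of the
#' generator frame) against dimer index and averages the slopes — the
#' coordinate-space analogue of the segment-based phi-slope statistic.
#'
#' @param lat An `mt_lattice` in the canonical generator frame.
#' @return List with `dphi_per_dimer` (degrees per dimer, mean over
#'   protofilaments), `per_pf` slopes and `theta` (degrees, from the
#'   closure at the measured mean radius).
#' @export
measure_skew <- function(lat) {
  stopifnot(inherits(lat, "mt_lattice"))
  dc <- dimer_coms(lat)
  per_pf <- vapply(split(dc, dc$pf), function(d) {
    if (nrow(d) < 2) return(NA_real_)
    az <- unwrap_series(atan2(d$y, d$x)[order(d$dimer)] * 180 / pi)
    unname(stats::coef(stats::lm(az ~ sort(d$dimer)))[2])
  }, numeric(1))
  mu <- mean(per_pf, na.rm = TRUE)
  r <- mean(sqrt(dc$x^2 + dc$y^2))
  a <- lat$spec$monomer_repeat
  list(dphi_per_dimer = mu, per_pf = per_pf,
       theta = atan(mu * (pi / 180) * r / (2 * a)) * 180 / pi)
}

#' Fit the rotation-per-dimer skew statistic from segment phi series
#'
#' Reproduces the per-microtubule skew measurement used on segment
#' alignment parameters: for every microtubule the observed phi angles are
#' unwrapped (successive differences mapped into one protofilament spacing,
#' `(-180/N, +180/N]` degrees), a least-squares line of phi against dimer
#' index is fitted, and the per-MT slopes are aggregated as mean +/- SD.
#' Positive slopes are right-handed skew (phi increasing toward the plus
#' end).
#'
#' @param segments Data frame with columns `mt_id`, `seg_index`, `z`
#'   (Angstrom) and `phi` (degrees; a `phi_obs` column is accepted too).
#' @param n_pf Protofilament number (sets the unwrap branch width).
#' @param dimer_repeat Dimer repeat in Angstrom (default 82).
#' @param radius Radius used to convert the slope to a skew angle theta.
#' @return List of class `skew_measurement`: `per_mt` slopes (deg/dimer),
#'   `mean`, `sd`, `dphi_per_dimer` (= mean) and `theta` (degrees, via the
#'   closure at `radius`).
#' @export
fit_phi_slope <- function(segments, n_pf = 13, dimer_repeat = 82,
                          radius = 105) {
  phi_col <- if ("phi" %in% names(segments)) "phi" else "phi_obs"
  stopifnot(all(c("mt_id", "z", phi_col) %in% names(segments)))
  period <- 360 / n_pf
  per_mt <- vapply(split(segments, segments$mt_id), function(s) {
    s <- s[order(s$z), ]
    if (nrow(s) < 3) stop("need >= 3 segments per MT")
    if (stats::sd(s$z) == 0) stop("all-identical z: slope undefined")
    phi <- unwrap_series(s[[phi_col]], period = period)
    di <- (s$z - s$z[1]) / dimer_repeat
    unname(stats::coef(stats::lm(phi ~ di))[2])
  }, numeric(1))
  a <- dimer_repeat / 2
  mu <- mean(per_mt)
  structure(list(per_mt = per_mt, mean = mu,
                 sd = if (length(per_mt) > 1) stats::sd(per_mt) else NA_real_,
                 dphi_per_dimer = mu,
                 theta = atan(mu * (pi / 180) * radius / (2 * a)) * 180 / pi),
            class = "skew_measurement")
}

#' @export
print.skew_measurement <- function(x, ...) {
  cat(sprintf(
    "Protofilament skew: dPHI = %.4f +/- %.4f deg/dimer over %d MTs (theta = %.4f deg)\n",
    x$mean, x$sd, length(x$per_mt), x$theta))
  invisible(x)
}
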