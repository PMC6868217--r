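## Seam-position / alpha-beta-register hypothesis bookkeeping: the 2N
## rigid transforms against which a pseudo-helical reconstruction pipeline
## classifies every microtubule, and the enumeration of CKK binding sites.

#' Apply a rigid transform to a lattice
#'
#' @param lat An `mt_lattice`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation (applied after rotation).
#' @return The transformed lattice (truth record unchanged apart from
#'   coordinates; use [apply_hypothesis()] for seam bookkeeping).
#' @export
transform_lattice <- function(lat, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  stopifnot(inherits(lat, "mt_lattice"))
  for (tab in c("atoms", "monomers")) {
    xyz <- apply_rigid(as.matrix(lat[[tab]][, c("x", "y", "z")]),
                       rotation, translation)
    lat[[tab]][, c("x", "y", "z")] <- xyz
  }
  lat
}

#' Enumerate the 2N seam-position / register hypotheses
#'
#' A pseudo-helical microtubule with N protofilaments admits N possible
#' seam positions, each with two alpha/beta registers (the register
#' counterpart is translated one monomer, +a, along the helical axis) —
#' 26 reference hypotheses for a 13-protofilament microtubule. Hypothesis
#' (k, rho) is the rigid transform composing the pseudo-helical symmetry
#' operator k times (rotation k*360/N about the axis, rise k*h) with the
#' optional one-monomer register shift rho*a.
#'
#' @param spec A [lattice_spec()] supplying N and, via the accommodation
#'   closure, the lateral rise h and monomer repeat a.
#' @return Data frame of class `seam_hypotheses` with columns `k`
#'   (seam position, 0..N-1), `register` (0/1), `rot_deg` (rotation about
#'   the axis, degrees) and `rise` (axial translation, Angstrom).
#'   Hypotheses whose transforms coincide within tolerance (1e-6 deg /
#'   1e-6 A) are collapsed with a warning; for any valid spec all 2N are
#'   distinct.
#' @examples
#' nrow(enumerate_seam_hypotheses(lattice_spec(n_pf = 13)))  # 26
#' @export
enumerate_seam_hypotheses <- function(spec) {
  validate_lattice_spec(spec)
  if (spec$n_pf < 8) stop("n_pf must be >= 8")
  sol <- accommodation_solve(spec)
  N <- spec$n_pf; a <- spec$monomer_repeat; h <- sol$h
  hyp <- expand.grid(register = 0:1, k = 0:(N - 1L))[, c("k", "register")]
  hyp$rot_deg <- hyp$k * (360 / N)
  hyp$rise <- hyp$k * h + hyp$register * a
  ## dedup by transform equality
  key_rot <- round(hyp$rot_deg %% 360, 6)
  key_rise <- round(hyp$rise, 6)
  dup <- duplicated(data.frame(key_rot, key_rise))
  if (any(dup)) {
    warning("degenerate lattice parameters: ", sum(dup),
            " duplicate seam/register transforms collapsed")
    hyp <- hyp[!dup, ]
  }
  rownames(hyp) <- NULL
  class(hyp) <- c("seam_hypotheses", "data.frame")
  hyp
}

#' Apply a seam/register hypothesis to a lattice
#'
#' Rigidly transforms a lattice generated at the reference hypothesis
#' (k = 0, rho = 0) by the hypothesis transform: rotation by k*360/N about
#' the z axis plus an axial translation k*h + rho*a. The truth record is
#' updated (seam junction advances by k, register flips with rho).
#'
#' @param lat An `mt_lattice` in the canonical generator frame.
#' @param k Seam position shift, integer in `[0, N)`.
#' @param register Register shift rho, 0 or 1.
#' @return The transformed `mt_lattice`.
#' @export
apply_hypothesis <- function(lat, k, register = 0) {
  stopifnot(inherits(lat, "mt_lattice"))
  N <- lat$spec$n_pf
  k <- as.integer(k); register <- as.integer(register)
  if (k < 0 || k >= N) stop("k must lie in [0, N)")
  if (!register %in% c(0L, 1L)) stop("register must be 0 or 1")
  sol <- accommodation_solve(lat$spec)
  rot <- rotation_z(k * 360 / N)
  tr <- c(0, 0, k * sol$h + register * lat$spec$monomer_repeat)
  out <- transform_lattice(lat, rot, tr)
  ## the rotation carries protofilament i to the azimuth of i + k:
  ## relabel so pf indices keep meaning "position around the wall"
  for (tab in c("atoms", "monomers"))
    out[[tab]]$pf <- (out[[tab]]$pf + k) %% N
  out$spec$seam_index <- (lat$spec$seam_index + k) %% N
  out$spec$pf_radial_offsets <-
    lat$spec$pf_radial_offsets[((0:(N - 1L)) - k) %% N + 1L]
  out$truth$seam_index <- (lat$truth$seam_index + k) %% N
  out$truth$register <- (lat$truth$register + register) %% 2L
  out$truth$hypothesis <- c(k = (lat$truth$hypothesis["k"] + k) %% N,
                            rho = (lat$truth$hypothesis["rho"] +
                                     register) %% 2L)
  names(out$truth$hypothesis) <- c("k", "rho")
  out
}

#' Enumerate CKK binding sites on a lattice
#'
#' CKK domains bind in the intradimer, interprotofilament cleft — one site
#' per non-seam lateral junction per dimer ring, placed at the midpoint of
#' the two laterally adjacent dimer centres of mass (the wedge between the
#' four monomers alpha1/beta1/alpha2/beta2). Successive sites on a
#' junction are one dimer repeat (~8 nm) apart along the axis, and the
#' seam junction carries no site.
#'
#' @param lat An `mt_lattice`.
#' @return Data frame with one row per site: `junction`, `pf_a`, `pf_b`,
#'   `dimer` (ring index) and site `x`, `y`, `z` (Angstrom).
#' @examples
#' lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 1))
#' nrow(enumerate_binding_sites(lat))  # 12 = N - 1
#' @export
enumerate_binding_sites <- function(lat) {
  stopifnot(inherits(lat, "mt_lattice"))
  N <- lat$spec$n_pf
  seam <- lat$truth$seam_index
  dc <- dimer_coms(lat)
  sites <- list()
  for (k in setdiff(0:(N - 1L), seam)) {
    a <- dc[dc$pf == k, ]
    b <- dc[dc$pf == (k + 1L) %% N, ]
    common <- intersect(a$dimer, b$dimer)
    if (!length(common)) next
    a <- a[match(common, a$dimer), ]
    b <- b[match(common, b$dimer), ]
    sites[[length(sites) + 1L]] <- data.frame(
      junction = k, pf_a = k, pf_b = (k + 1L) %% N, dimer = common,
      x = (a$x + b$x) / 2, y = (a$y + b$y) / 2, z = (a$z + b$z) / 2)
  }
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  out
}
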