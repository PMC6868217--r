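#' Parametric specification of a pseudo-helical microtubule lattice
#'
#' Describes a B-lattice microtubule built from N protofilaments of
#' alpha/beta-tubulin dimers, with a single A-lattice seam, an S-start
#' monomer helix (S = 3 for canonical microtubules), and a protofilament
#' skew realized by one of two mechanisms (whole-protofilament tilt or
#' interdimer stagger). The skew can be supplied as the protofilament skew
#' angle theta (degrees), the lateral monomer rise h (Angstrom), or the
#' rotation-per-dimer dPHI (degrees per dimer); the remaining two quantities
#' follow from the lattice accommodation closure (see
#' [accommodation_solve()]).
#'
#' @param n_pf Number of protofilaments N (8..17; microtubules in vitro are
#'   mostly 13 or 14).
#' @param start Monomer-based helix start number S (default 3, the canonical
#'   3-start lattice).
#' @param monomer_repeat Axial monomer spacing a in Angstrom along a
#'   protofilament (default 41, so the dimer repeat is 82 Angstrom).
#' @param radius Radial distance of monomer centres from the helical axis in
#'   Angstrom (default 105; only diameter *differences* are meaningful, see
#'   the methods vignette).
#' @param skew_mode One of `"by_theta"`, `"by_rise"`, `"by_dphi"`: which of
#'   the three coupled skew parameters `skew_value` supplies.
#' @param skew_value Skew angle theta in degrees, lateral rise h in
#'   Angstrom, or dPHI in degrees per dimer, according to `skew_mode`.
#'   Positive theta / dPHI is right-handed skew (azimuth increases toward
#'   the plus end).
#' @param mechanism How a non-zero skew is realized: `"none"` (bodies
#'   axis-aligned; meaningful for zero skew), `"tilt"` (each protofilament
#'   tilted rigidly about its radial axis), or `"stagger"` (dimer bodies
#'   stay axis-aligned, successive dimers offset tangentially).
#' @param seam_index Lateral junction (0-based, junction k lies between
#'   protofilaments k and k+1 mod N) carrying the A-lattice seam contact.
#' @param register Global alpha/beta register, 0 or 1; register 1 translates
#'   the decorated lattice by one monomer (+a) along the axis.
#' @param n_dimers Dimers per protofilament.
#' @param pf_radial_offsets Per-protofilament radial displacement in
#'   Angstrom (length N, default all zero).
#' @param lateral_compression Reduction, in Angstrom, of the
#'   centre-of-mass separation between laterally adjacent dimers (applied as
#'   a uniform radial contraction; default 0).
#' @param coord_noise_sd Isotropic Gaussian jitter (Angstrom) added to every
#'   pseudo-atom.
#' @param seed Integer seed governing all randomness of the realization.
#' @return An object of class `lattice_spec`.
#' @seealso [build_lattice()], [accommodation_solve()]
#' @examples
#' spec <- lattice_spec(n_pf = 13)
#' accommodation_solve(spec)
#' @export
lattice_spec <- function(n_pf = 13, start = 3, monomer_repeat = 41,
                         radius = 105,
                         skew_mode = c("by_theta", "by_rise", "by_dphi"),
                         skew_value = 0,
                         mechanism = c("none", "tilt", "stagger"),
                         seam_index = 0, register = 0, n_dimers = 4,
                         pf_radial_offsets = NULL, lateral_compression = 0,
                         coord_noise_sd = 0, seed = 1L) {
  skew_mode <- match.arg(skew_mode)
  mechanism <- match.arg(mechanism)
  pf_radial_offsets <- pf_radial_offsets %||% numeric(n_pf)
  spec <- structure(list(
    n_pf = as.integer(n_pf), start = as.integer(start),
    monomer_repeat = monomer_repeat, radius = radius,
    skew_mode = skew_mode, skew_value = skew_value, mechanism = mechanism,
    seam_index = as.integer(seam_index), register = as.integer(register),
    n_dimers = as.integer(n_dimers),
    pf_radial_offsets = pf_radial_offsets,
    lateral_compression = lateral_compression,
    coord_noise_sd = coord_noise_sd, seed = as.integer(seed)
  ), class = "lattice_spec")
  validate_lattice_spec(spec)
  spec
}

validate_lattice_spec <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (spec$n_pf < 8 || spec$n_pf > 17)
    stop("n_pf must be in 8..17, got ", spec$n_pf)
  if (spec$start < 1) stop("start number S must be >= 1")
  if (spec$monomer_repeat <= 0) stop("monomer_repeat must be positive")
  if (spec$radius <= 0) stop("radius must be positive")
  if (spec$seam_index < 0 || spec$seam_index >= spec$n_pf)
    stop("seam_index must lie in [0, n_pf)")
  if (!spec$register %in% c(0L, 1L)) stop("register must be 0 or 1")
  if (spec$n_dimers < 1) stop("n_dimers must be >= 1")
  if (length(spec$pf_radial_offsets) != spec$n_pf)
    stop("pf_radial_offsets must have length n_pf")
  if (spec$coord_noise_sd < 0) stop("coord_noise_sd must be >= 0")
  if (spec$lateral_compression < 0)
    stop("lateral_compression must be >= 0")
  ## closure must be solvable (errors if non-physical)
  accommodation_solve(spec)
  invisible(spec)
}

#' @export
print.lattice_spec <- function(x, ...) {
  sol <- accommodation_solve(x)
  cat(sprintf(
    paste0("Microtubule lattice spec: %d pf, %d-start, a = %g A, r = %g A, ",
           "%d dimers/pf\n  seam at junction %d, register %d, mechanism %s\n",
           "  skew: theta = %.4f deg, h = %.4f A, dPHI = %.4f deg/dimer\n"),
    x$n_pf, x$start, x$monomer_repeat, x$radius, x$n_dimers,
    x$seam_index, x$register, x$mechanism,
    sol$theta, sol$h, sol$dphi_per_dimer))
  invisible(x)
}

#' Solve the lattice accommodation closure
#'
#' The lattice accommodation model couples protofilament number N, start
#' number S, monomer repeat a, radius r, lateral monomer rise h and
#' protofilament skew angle theta through the closure relation
#' \deqn{\tan\theta = (S a - N h) / (2 \pi r)}
#' and the per-dimer rotation
#' \deqn{\Delta\Phi = (2 a \tan\theta / r) \cdot (180/\pi).}
#' Exactly one of theta / h / dPHI is free (chosen by the spec's
#' `skew_mode`); this function returns the mutually consistent triple.
#' Positive theta means right-handed skew: the protofilament azimuth
#' increases toward the plus end. A 14-protofilament lattice holding the
#' 13-protofilament ideal rise therefore solves to a negative (left-handed)
#' skew, and 13-protofilament lattices with S = 3 and theta = 0 have
#' h = 3a/13.
#'
#' @param spec A [lattice_spec()].
#' @return List with elements `theta` (degrees), `h` (Angstrom) and
#'   `dphi_per_dimer` (degrees per dimer).
#' @examples
#' accommodation_solve(lattice_spec(n_pf = 13))           # h = 3*41/13
#' accommodation_solve(lattice_spec(n_pf = 14, skew_mode = "by_rise",
#'                                  skew_value = 3 * 41 / 13))  # theta < 0
#' @export
accommodation_solve <- function(spec) {
  N <- spec$n_pf; S <- spec$start; a <- spec$monomer_repeat; r <- spec$radius
  v <- spec$skew_value
  tt <- switch(spec$skew_mode,
    by_theta = {
      if (abs(v) >= 90) stop("non-physical spec: |theta| >= 90 degrees")
      tan(v * pi / 180)
    },
    by_rise = (S * a - N * v) / (2 * pi * r),
    by_dphi = v * (pi / 180) * r / (2 * a)
  )
  theta <- atan(tt) * 180 / pi
  h <- (S * a - 2 * pi * r * tt) / N
  dphi <- (2 * a * tt / r) * (180 / pi)
  if (abs(theta) >= 90) stop("non-physical spec: |theta| >= 90 degrees")
  if (h <= 0) stop("non-physical spec: lateral rise h <= 0 after closure")
  list(theta = theta, h = h, dphi_per_dimer = dphi)
}
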