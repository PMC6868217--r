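## Realization of a lattice_spec as pseudo-atom coordinates.
##
## Each tubulin monomer is a small rigid body of 5 labelled pseudo-atoms
## spanning ~20 A, so that RMSD profiles behave like backbone RMSD and
## whole-protofilament tilt is distinguishable from interdimer stagger
## (point monomers cannot tell the two apart).

## Canonical monomer body template, centred on the monomer centre.
## Asymmetric on purpose: a rotated body is never congruent to an
## unrotated one, which is what makes orientation observable.
monomer_body_template <- function() {
  tpl <- rbind(
    c(0,  0,  9),
    c(0,  0, -9),
    c(4,  0,  3),
    c(-4, 0, -3),
    c(0,  4,  0))
  sweep(tpl, 2, colMeans(tpl))
}

#' Build a pseudo-helical microtubule lattice
#'
#' Realizes a [lattice_spec()] as coordinates. Monomer j on the
#' protofilament with helical order m sits at axial position
#' `z = j*a + m*h + register*a` and azimuth
#' `phi = k*(360/N) + z * dPHI/(2a)` (continuous drift; for the
#' `"stagger"` mechanism the drift advances per dimer instead), at radius
#' `r + dr_k`. The helical order `m = (k - seam_index - 1) mod N` places
#' the lattice wrap - and with it the single A-lattice seam of an
#' odd-start B-lattice - at junction `seam_index`. The `"tilt"` mechanism
#' rotates every body rigidly about its radial axis by the skew angle
#' theta, so each protofilament remains a straight tilted rod; the
#' `"stagger"` mechanism keeps bodies axis-aligned and offsets successive
#' dimers tangentially by the same per-dimer increment.
#'
#' @param spec A [lattice_spec()].
#' @return An object of class `mt_lattice`: list with elements `spec`,
#'   `monomers` (one row per monomer: pf, helical order m, axial index j,
#'   kind, dimer, centre x/y/z), `atoms` (one row per pseudo-atom) and
#'   `truth` (realized theta, h, dPHI-per-dimer, effective radius,
#'   diameter, seam junction, register, mechanism).
#' @examples
#' lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 3))
#' nrow(lat$monomers)  # 13 * 2 * 3
#' @export
build_lattice <- function(spec) {
  validate_lattice_spec(spec)
  sol <- accommodation_solve(spec)
  N <- spec$n_pf; a <- spec$monomer_repeat
  h <- sol$h; theta <- sol$theta; dphi <- sol$dphi_per_dimer
  n_mono <- 2L * spec$n_dimers

  ## lateral compression: uniform radial contraction solved exactly so the
  ## adjacent-dimer COM separation shrinks by the requested amount
  r_eff <- spec$radius
  if (spec$lateral_compression > 0) {
    chord0 <- 2 * r_eff * sin(pi / N)
    sep0 <- sqrt(chord0^2 + h^2)
    sep1 <- sep0 - spec$lateral_compression
    if (sep1 <= h) stop("lateral_compression too large: separation <= rise")
    r_eff <- sqrt(sep1^2 - h^2) / (2 * sin(pi / N))
  }
  r_k <- r_eff + spec$pf_radial_offsets
  if (any(r_k <= 0)) stop("negative resulting radius for some protofilament")

  pf <- rep(0:(N - 1L), each = n_mono)
  m_of_pf <- (0:(N - 1L) - spec$seam_index - 1L) %% N
  m <- m_of_pf[pf + 1L]
  j <- rep(0:(n_mono - 1L), times = N)
  z <- j * a + m * h + spec$register * a
  dimer <- j %/% 2L
  kind <- ifelse(j %% 2L == 0L, "alpha", "beta")

  base_az <- pf * (360 / N)
  drift <- if (spec$mechanism == "stagger") dimer * dphi else z * dphi / (2 * a)
  az <- (base_az + drift) * pi / 180

  rad <- r_k[pf + 1L]
  cx <- rad * cos(az); cy <- rad * sin(az); cz <- z

  ## body atoms: template rotated about local x (radial axis) for tilt,
  ## then about z by the monomer azimuth, then translated to the centre
  tpl <- monomer_body_template()
  alpha_tilt <- if (spec$mechanism == "tilt") -theta else 0
  B <- rotation_about_axis(c(1, 0, 0), alpha_tilt) %*% t(tpl)  # 3 x 5
  n_atoms_per <- nrow(tpl)
  idx <- rep(seq_along(cx), each = n_atoms_per)
  at <- rep(seq_len(n_atoms_per), times = length(cx))
  ca <- cos(az)[idx]; sa <- sin(az)[idx]
  bx <- B[1, at]; by <- B[2, at]; bz <- B[3, at]
  ax <- cx[idx] + bx * ca - by * sa
  ay <- cy[idx] + bx * sa + by * ca
  azl <- cz[idx] + bz

  if (spec$coord_noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(3 * length(ax),
                                           sd = spec$coord_noise_sd),
                              ncol = 3))
    ax <- ax + noise[, 1]; ay <- ay + noise[, 2]; azl <- azl + noise[, 3]
  }

  atoms <- data.frame(
    pf = pf[idx], m = m[idx], j = j[idx], kind = kind[idx],
    dimer = dimer[idx], atom = at, x = ax, y = ay, z = azl)

  ## monomer centres as centroids of (possibly noisy) body atoms, so
  ## coordinate noise propagates into downstream COM measurements
  mono_xyz <- cbind(
    x = colMeans(matrix(ax, nrow = n_atoms_per)),
    y = colMeans(matrix(ay, nrow = n_atoms_per)),
    z = colMeans(matrix(azl, nrow = n_atoms_per)))
  monomers <- data.frame(pf = pf, m = m, j = j, kind = kind, dimer = dimer,
                         mono_xyz)

  truth <- list(theta = theta, h = h, dphi_per_dimer = dphi,
                radius_eff = r_eff, per_pf_radii = r_k,
                diameter = 2 * mean(r_k),
                seam_index = spec$seam_index, register = spec$register,
                mechanism = spec$mechanism,
                hypothesis = c(k = 0L, rho = 0L))
  structure(list(spec = spec, monomers = monomers, atoms = atoms,
                 truth = truth),
            class = "mt_lattice")
}

#' @export
print.mt_lattice <- function(x, ...) {
  cat(sprintf(
    paste0("Microtubule lattice: %d pf x %d dimers (%d monomers, %d ",
           "pseudo-atoms)\n  seam junction %d, register %d, mechanism %s, ",
           "dPHI = %.4f deg/dimer, diameter = %.2f A\n"),
    x$spec$n_pf, x$spec$n_dimers, nrow(x$monomers), nrow(x$atoms),
    x$truth$seam_index, x$truth$register, x$truth$mechanism,
    x$truth$dphi_per_dimer, x$truth$diameter))
  invisible(x)
}

#' Perturb a lattice (radial offsets, lateral compression, noise)
#'
#' Returns a new lattice rebuilt from the original spec with the supplied
#' perturbations substituted; the input lattice is untouched and its truth
#' record is updated in the result. Emulates the binding-site remodelling
#' observed on CKK-decorated microtubules: asymmetric inward protofilament
#' shifts (0.4-1.5 A scale), compression of adjacent-dimer spacing, and
#' coordinate-level noise.
#'
#' @param lat An `mt_lattice`.
#' @param pf_radial_offsets Replacement per-protofilament radial offsets
#'   (length N), or NULL to keep the current ones.
#' @param lateral_compression Replacement lateral compression in Angstrom,
#'   or NULL.
#' @param coord_noise_sd Replacement coordinate noise SD, or NULL.
#' @param seed Replacement seed, or NULL.
#' @return A new `mt_lattice`.
#' @export
perturb_lattice <- function(lat, pf_radial_offsets = NULL,
                            lateral_compression = NULL,
                            coord_noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(lat, "mt_lattice"))
  spec <- lat$spec
  if (!is.null(pf_radial_offsets)) {
    if (length(pf_radial_offsets) != spec$n_pf)
      stop("pf_radial_offsets must have length n_pf")
    spec$pf_radial_offsets <- pf_radial_offsets
  }
  if (!is.null(lateral_compression))
    spec$lateral_compression <- lateral_compression
  if (!is.null(coord_noise_sd)) spec$coord_noise_sd <- coord_noise_sd
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  build_lattice(spec)
}

#' Average replicate lattices atom-wise
#'
#' Coordinate-wise mean over lattices sharing a topology — the synthetic
#' analogue of the segment averaging a reconstruction pipeline performs
#' before classification (averaging K independent noise realizations
#' reduces the coordinate noise by sqrt(K) while leaving the geometry
#' untouched).
#'
#' @param lats List of `mt_lattice` objects with identical topology.
#' @return An `mt_lattice` with averaged coordinates (spec and truth from
#'   the first element).
#' @export
average_lattices <- function(lats) {
  stopifnot(length(lats) >= 1,
            all(vapply(lats, inherits, logical(1), "mt_lattice")))
  out <- lats[[1]]
  for (v in c("x", "y", "z")) {
    out$atoms[[v]] <- rowMeans(vapply(lats, function(l) l$atoms[[v]],
                                      numeric(nrow(out$atoms))))
    out$monomers[[v]] <- rowMeans(vapply(lats, function(l) l$monomers[[v]],
                                         numeric(nrow(out$monomers))))
  }
  out
}

#' Dimer centres of mass
#'
#' @param lat An `mt_lattice`.
#' @return Data frame with one row per dimer: pf, helical order m, dimer
#'   index, and COM x/y/z (mean of the two monomer centres).
#' @export
dimer_coms <- function(lat) {
  mm <- lat$monomers
  key <- interaction(mm$pf, mm$dimer, drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  out <- data.frame(pf = tapply(mm$pf, key, `[`, 1),
                    m = tapply(mm$m, key, `[`, 1),
                    dimer = tapply(mm$dimer, key, `[`, 1),
                    x = agg(mm$x), y = agg(mm$y), z = agg(mm$z))
  out <- out[order(out$pf, out$dimer), ]
  rownames(out) <- NULL
  out
}

#' Classify the lateral junctions of a lattice as A- or B-lattice
#'
#' For each junction (protofilament k against k+1 mod N) every monomer is
#' paired with its nearest axial neighbour across the junction; a junction
#' is A-lattice (seam) when the paired kinds differ (alpha against beta)
#' for the majority of pairs, B-lattice when they agree. A canonical
#' odd-start B-lattice has exactly one A-lattice junction.
#'
#' @param lat An `mt_lattice`.
#' @return Data frame with columns `junction`, `pf_a`, `pf_b`,
#'   `a_lattice` (logical).
#' @export
lattice_junctions <- function(lat) {
  mm <- lat$monomers
  N <- lat$spec$n_pf
  half_a <- lat$spec$monomer_repeat / 2
  res <- lapply(0:(N - 1L), function(k) {
    a <- mm[mm$pf == k, ]
    b <- mm[mm$pf == (k + 1L) %% N, ]
    ## nearest axial neighbour across the junction; pairs further than
    ## half a monomer repeat have their true partner clipped off the
    ## lattice edge and are skipped
    differs <- vapply(seq_len(nrow(a)), function(i) {
      dz <- abs(b$z - a$z[i])
      if (min(dz) > half_a) return(NA)
      b$kind[which.min(dz)] != a$kind[i]
    }, logical(1))
    data.frame(junction = k, pf_a = k, pf_b = (k + 1L) %% N,
               a_lattice = mean(differs, na.rm = TRUE) > 0.5)
  })
  do.call(rbind, res)
}
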