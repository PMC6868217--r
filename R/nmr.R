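## NMR observables for CKK domain rigidity analysis: combined
## chemical-shift perturbation, CPMG relaxation-dispersion flatness, CEST
## minor-dip scanning, assignment transfer by spectral proximity, and
## assignment completeness.

#' Combined amide chemical-shift perturbation
#'
#' Combines the 1H and 15N shift changes (both in ppm) of an amide group
#' as \deqn{CSP = \sqrt{(0.15\,\Delta N)^2 + \Delta H^2}} — the 15N change
#' down-weighted by 0.15 to account for its larger shift range.
#'
#' @param dH Amide proton shift change, ppm (vectorized).
#' @param dN Amide nitrogen shift change, ppm.
#' @return Combined CSP in ppm.
#' @examples
#' csp(0.3, 2.0)  # sqrt(0.09 + 0.09) = 0.4243
#' @export
csp <- function(dH, dN) {
  stopifnot(all(is.finite(dH)), all(is.finite(dN)))
  sqrt((0.15 * dN)^2 + dH^2)
}

#' CPMG fields used by the dispersion experiments
#'
#' The refocusing frequencies (Hz) of the relaxation-dispersion series:
#' 50 to 1250 in steps of 100, then 1400 and 1500 Hz, all applied for a
#' constant transverse relaxation time of 40 ms.
#'
#' @return Numeric vector of 15 frequencies in Hz.
#' @export
cpmg_fields <- function() c(seq(50, 1250, by = 100), 1400, 1500)

#' Dispersion flatness: SD-to-mean ratio of CPMG peak intensities
#'
#' For a residue without millisecond conformational exchange the peak
#' intensity is independent of the CPMG refocusing frequency, so the ratio
#' of the standard deviation to the mean of the intensities across fields
#' is small; exchange produces frequency-dependent intensities and a large
#' ratio. Scale-invariant by construction.
#'
#' @param intensities Peak intensities across CPMG fields (>= 2 values).
#' @return SD/mean ratio (dimensionless).
#' @export
cpmg_flatness <- function(intensities) {
  if (length(intensities) < 2) stop("need >= 2 intensities")
  m <- mean(intensities)
  if (m == 0) stop("mean intensity is zero: ratio undefined")
  stats::sd(intensities) / m
}

#' Simulate a CPMG intensity series under two-state fast exchange
#'
#' Forward model for the dispersion oracle: the effective transverse rate
#' follows the fast-exchange (Luz-Meiboom) expression
#' \deqn{R_{2,eff}(\nu) = R_2^0 + \frac{p_A p_B \Delta\omega^2}{k_{ex}}
#'   \left(1 - \frac{4\nu}{k_{ex}} \tanh\frac{k_{ex}}{4\nu}\right)}
#' and intensities decay over the constant relaxation time,
#' `I = I0 * exp(-R2eff * t_relax)`. With `dw = 0` the profile is flat.
#'
#' @param fields CPMG frequencies in Hz (default [cpmg_fields()]).
#' @param r20 Exchange-free transverse rate, 1/s.
#' @param kex Exchange rate, 1/s.
#' @param pa Major-state population (pB = 1 - pA).
#' @param dw Chemical-shift difference between states, rad/s.
#' @param t_relax Constant relaxation time, s (default 0.04).
#' @param i0 Reference intensity.
#' @param noise_sd Gaussian intensity noise SD.
#' @param seed Seed for the noise draw.
#' @return Data frame with `field_hz` and `intensity`.
#' @export
simulate_cpmg_series <- function(fields = cpmg_fields(), r20 = 10,
                                 kex = 1000, pa = 0.97, dw = 0,
                                 t_relax = 0.04, i0 = 100,
                                 noise_sd = 0, seed = 1L) {
  pb <- 1 - pa
  rex <- if (dw == 0) rep(0, length(fields)) else
    (pa * pb * dw^2 / kex) * (1 - (4 * fields / kex) *
                                tanh(kex / (4 * fields)))
  r2eff <- r20 + rex
  inten <- i0 * exp(-r2eff * t_relax)
  if (noise_sd > 0)
    inten <- inten + with_seed(seed, stats::rnorm(length(inten),
                                                  sd = noise_sd))
  data.frame(field_hz = fields, intensity = inten)
}

#' Default CEST saturation offsets
#'
#' @return Offsets in Hz from 8200 down to 6325 with 25 Hz spacing.
#' @export
cest_offsets <- function() seq(8200, 6325, by = -25)

#' Simulate a CEST intensity profile
#'
#' Normalized intensity against saturation offset, with a main-resonance
#' dip and optionally one sparsely populated minor-state dip, both
#' Lorentzian, plus Gaussian noise.
#'
#' @param offsets Saturation offsets, Hz (default [cest_offsets()]).
#' @param main_offset Main resonance position, Hz.
#' @param main_depth Main dip depth (fraction of the baseline, e.g. 0.8).
#' @param minor_offset Minor-state dip position, Hz (NULL for none).
#' @param minor_depth Minor dip depth.
#' @param width Lorentzian half-width, Hz.
#' @param noise_sd Gaussian noise SD on the normalized intensity.
#' @param seed Seed for the noise draw.
#' @return Data frame with `offset_hz` and `intensity` (normalized).
#' @export
simulate_cest_profile <- function(offsets = cest_offsets(),
                                  main_offset = 7600, main_depth = 0.8,
                                  minor_offset = NULL, minor_depth = 0,
                                  width = 40, noise_sd = 0.01,
                                  seed = 1L) {
  lor <- function(x, x0) 1 / (1 + ((x - x0) / width)^2)
  inten <- 1 - main_depth * lor(offsets, main_offset)
  if (!is.null(minor_offset))
    inten <- inten - minor_depth * lor(offsets, minor_offset)
  if (noise_sd > 0)
    inten <- inten + with_seed(seed, stats::rnorm(length(inten),
                                                  sd = noise_sd))
  data.frame(offset_hz = offsets, intensity = inten)
}

#' Scan a CEST profile for minor-state dips
#'
#' Flags offsets whose intensity drops more than `3 * noise_sd` below the
#' baseline (median intensity), groups contiguous flagged offsets into
#' dips, and discards the main-resonance dip (the one containing the
#' global minimum). A residue without slow millisecond exchange yields an
#' empty minor-dip list.
#'
#' @param profile Data frame with `offset_hz` and `intensity` (>= 5
#'   points).
#' @param noise_sd Intensity noise level defining the 3-sigma detection
#'   threshold.
#' @return Data frame of minor dips (`offset_hz` at the dip minimum,
#'   `depth` below baseline), zero rows if none.
#' @export
cest_dip_scan <- function(profile, noise_sd) {
  stopifnot(all(c("offset_hz", "intensity") %in% names(profile)))
  if (nrow(profile) < 5) stop("need >= 5 profile points")
  profile <- profile[order(profile$offset_hz), ]
  baseline <- stats::median(profile$intensity)
  below <- profile$intensity < baseline - 3 * noise_sd
  if (!any(below)) return(data.frame(offset_hz = numeric(0),
                                     depth = numeric(0)))
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dips <- data.frame(start = starts[runs$values],
                     end = ends[runs$values])
  dips$min_idx <- vapply(seq_len(nrow(dips)), function(i) {
    ii <- dips$start[i]:dips$end[i]
    ii[which.min(profile$intensity[ii])]
  }, integer(1))
  ## exclude the main-resonance dip: the run containing the global minimum
  gmin <- which.min(profile$intensity)
  keep <- !(dips$start <= gmin & gmin <= dips$end)
  dips <- dips[keep, , drop = FALSE]
  data.frame(offset_hz = profile$offset_hz[dips$min_idx],
             depth = baseline - profile$intensity[dips$min_idx])
}

#' Transfer resonance assignments by spectral proximity
#'
#' Matches solution-state assignments to observed (e.g. solid-state) peaks
#' assuming spectral proximity in the independent HN, N and CA dimensions:
#' a candidate pair must agree within the per-dimension tolerance in every
#' dimension present in both tables, pairs are ranked by
#' tolerance-scaled Euclidean distance, and matches are accepted greedily
#' so that each accepted pair is mutual-nearest among the remaining
#' candidates. Default tolerances follow the determined signal linewidths
#' (0.1 ppm in 1H, 0.6 ppm in 15N) plus a configurable 0.5 ppm for CA.
#'
#' @param solution Data frame with `residue_id`, `HN`, `N` and optionally
#'   `CA` (ppm).
#' @param observed Data frame with `peak_id` (or `residue_id`), `HN`, `N`,
#'   optionally `CA`.
#' @param tol Named per-dimension tolerances in ppm
#'   (default `c(HN = 0.1, N = 0.6, CA = 0.5)`).
#' @return List with `matches` (residue_id, peak_id, per-dimension
#'   deviations, scaled distance), `unmatched_solution` and
#'   `unmatched_peaks`.
#' @export
transfer_assignments <- function(solution, observed,
                                 tol = c(HN = 0.1, N = 0.6, CA = 0.5)) {
  stopifnot(nrow(solution) > 0, nrow(observed) > 0)
  if (!"peak_id" %in% names(observed)) {
    observed$peak_id <- observed$residue_id %||% seq_len(nrow(observed))
  }
  dims <- intersect(c("HN", "N", "CA"), intersect(names(solution),
                                                  names(observed)))
  dims <- dims[vapply(dims, function(d) {
    !all(is.na(solution[[d]])) && !all(is.na(observed[[d]]))
  }, logical(1))]
  if (!length(dims)) stop("no shared shift dimensions")

  cand <- NULL
  for (i in seq_len(nrow(solution))) {
    dev <- lapply(dims, function(d) observed[[d]] - solution[[d]][i])
    names(dev) <- dims
    ok <- rep(TRUE, nrow(observed))
    d2 <- rep(0, nrow(observed))
    for (d in dims) {
      ok <- ok & !is.na(dev[[d]]) & abs(dev[[d]]) <= tol[[d]]
      d2 <- d2 + (dev[[d]] / tol[[d]])^2
    }
    if (any(ok)) {
      add <- data.frame(sol = i, obs = which(ok),
                        dist = sqrt(d2[ok]))
      for (d in dims) add[[paste0("d", d)]] <- dev[[d]][ok]
      cand <- rbind(cand, add)
    }
  }
  matches <- data.frame(residue_id = solution$residue_id[0],
                        peak_id = observed$peak_id[0])
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), ]
    used_s <- logical(nrow(solution)); used_o <- logical(nrow(observed))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_s[cand$sol[r]] && !used_o[cand$obs[r]]) {
        keep[r] <- TRUE
        used_s[cand$sol[r]] <- TRUE
        used_o[cand$obs[r]] <- TRUE
      }
    }
    cand <- cand[keep, ]
    matches <- data.frame(residue_id = solution$residue_id[cand$sol],
                          peak_id = observed$peak_id[cand$obs],
                          dist = cand$dist)
    for (d in dims) matches[[paste0("d", d)]] <- cand[[paste0("d", d)]]
  }
  list(matches = matches,
       unmatched_solution =
         setdiff(solution$residue_id, matches$residue_id),
       unmatched_peaks = setdiff(observed$peak_id, matches$peak_id))
}

#' Assignment completeness over a construct range
#'
#' Percentage of residues in the construct range that are assigned:
#' `100 * |assigned intersect range| / |range|`. The exact ratio is
#' returned; rounding is left to the caller.
#'
#' @param assigned_ids Integer residue numbers with assignments.
#' @param construct_range Integer range of the construct (e.g.
#'   `1474:1613`).
#' @return Percentage (0..100).
#' @examples
#' assignment_completeness(seq_len(124) + 1473, 1474:1613)  # 88.57...
#' @export
assignment_completeness <- function(assigned_ids, construct_range) {
  if (!length(construct_range)) stop("empty construct range")
  100 * length(intersect(assigned_ids, construct_range)) /
    length(construct_range)
}
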