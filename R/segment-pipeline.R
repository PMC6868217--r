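## Desk-scale simulation of the per-microtubule restraint logic used when
## processing pseudo-helical microtubule segments: protofilament-number
## classification by modal class, the median-phi restraint, and
## seam/register voting. Classification is modelled as a categorical noise
## channel (correct with stated probability, otherwise uniform over the
## alternatives), which makes the restraint logic testable without any
## density-space computation.

#' Simulate a segment dataset with per-segment observation noise
#'
#' Each microtubule contributes `n_seg` boxed segments spaced one dimer
#' repeat (82 Angstrom) apart. Per segment, the observed phi angle is the
#' true phi plus Gaussian noise, with a stated fraction replaced by uniform
#' outliers; the protofilament-number call and the seam/register-hypothesis
#' call are correct with stated probability, otherwise uniform over the
#' remaining alternatives.
#'
#' @param n_mt Number of microtubules.
#' @param n_seg Segments per microtubule (default 11; a ~0.9 micron
#'   microtubule boxed every 82 Angstrom).
#' @param pf_classes Candidate protofilament numbers (class space 11..16).
#' @param pf_probs Sampling probabilities of the true pf number (defaults
#'   to an even 13/14 mix).
#' @param dphi_per_dimer True skew slope in degrees per dimer (phi trend
#'   along the microtubule; default 0).
#' @param phi_sd Gaussian phi noise SD, degrees.
#' @param outlier_frac Fraction of segments whose phi is replaced by a
#'   uniform draw on [0, 360).
#' @param class_error Per-segment probability of a wrong pf-number call.
#' @param hyp_error Per-segment probability of a wrong seam/register call
#'   (hypothesis space has 2N entries for a true N-pf microtubule).
#' @param dimer_repeat Segment spacing in Angstrom (default 82).
#' @param seed Integer seed.
#' @return List with `segments` (data frame: mt_id, seg_index, z, phi_true,
#'   phi_obs, class_true, class_obs, hyp_true, hyp_obs) and `truth` (per-MT
#'   data frame: mt_id, n_pf, phi0, dphi_per_dimer, hyp_k, hyp_rho, hyp)
#'   where hypothesis index = 2*k + rho.
#' @export
simulate_segment_dataset <- function(n_mt = 50, n_seg = 11,
                                     pf_classes = 11:16,
                                     pf_probs = NULL,
                                     dphi_per_dimer = 0,
                                     phi_sd = 0, outlier_frac = 0,
                                     class_error = 0, hyp_error = 0,
                                     dimer_repeat = 82, seed = 1L) {
  if (is.null(pf_probs)) {
    pf_probs <- rep(0, length(pf_classes))
    pf_probs[pf_classes %in% c(13, 14)] <- 1
    if (all(pf_probs == 0)) pf_probs <- rep(1, length(pf_classes))
  }
  pf_probs <- pf_probs / sum(pf_probs)
  with_seed(seed, {
    n_pf <- sample(pf_classes, n_mt, replace = TRUE, prob = pf_probs)
    phi0 <- stats::runif(n_mt, 0, 360)
    hyp_k <- vapply(n_pf, function(N) sample(0:(N - 1L), 1L), integer(1))
    hyp_rho <- sample(0:1, n_mt, replace = TRUE)
    truth <- data.frame(mt_id = seq_len(n_mt), n_pf = n_pf, phi0 = phi0,
                        dphi_per_dimer = dphi_per_dimer,
                        hyp_k = hyp_k, hyp_rho = hyp_rho,
                        hyp = 2L * hyp_k + hyp_rho)

    mt_id <- rep(seq_len(n_mt), each = n_seg)
    seg_index <- rep(seq_len(n_seg) - 1L, times = n_mt)
    z <- seg_index * dimer_repeat
    phi_true <- (phi0[mt_id] + dphi_per_dimer * seg_index) %% 360
    phi_obs <- (phi_true + stats::rnorm(length(phi_true), 0, phi_sd)) %% 360
    is_out <- stats::runif(length(phi_obs)) < outlier_frac
    phi_obs[is_out] <- stats::runif(sum(is_out), 0, 360)

    ## categorical noise channel for the pf-number call
    class_true <- n_pf[mt_id]
    class_obs <- class_true
    wrong <- stats::runif(length(class_obs)) < class_error
    if (any(wrong)) {
      class_obs[wrong] <- vapply(class_true[wrong], function(tr) {
        sample(setdiff(pf_classes, tr), 1L)
      }, numeric(1))
    }

    ## categorical noise channel for the seam/register call, 2N-way per MT
    hyp_true <- truth$hyp[mt_id]
    hyp_obs <- hyp_true
    wrongh <- stats::runif(length(hyp_obs)) < hyp_error
    if (any(wrongh)) {
      nh <- 2L * n_pf[mt_id]
      hyp_obs[wrongh] <- vapply(which(wrongh), function(i) {
        sample(setdiff(0:(nh[i] - 1L), hyp_true[i]), 1L)
      }, numeric(1))
    }

    segments <- data.frame(mt_id = mt_id, seg_index = seg_index, z = z,
                           phi_true = phi_true, phi_obs = phi_obs,
                           class_true = class_true, class_obs = class_obs,
                           hyp_true = hyp_true, hyp_obs = hyp_obs)
    list(segments = segments, truth = truth)
  })
}

## Modal value with the documented tie-break: among tied values, pick the
## one whose earliest occurrence (lowest seg_index) comes first.
modal_call <- function(values, seg_index) {
  tab <- table(values)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    firsts <- vapply(top, function(v) min(seg_index[values == v]),
                     numeric(1))
    top <- top[which.min(firsts)]
  }
  v <- utils::type.convert(top, as.is = TRUE)
  v
}

#' Assign each microtubule the modal protofilament-number class
#'
#' All segments of a microtubule receive the modal class of that
#' microtubule's per-segment calls; ties are broken toward the class whose
#' earliest segment occurs first (deterministic).
#'
#' @param segments Segment data frame with `mt_id`, `seg_index`,
#'   `class_obs`.
#' @return Data frame with `mt_id` and the assigned `class`.
#' @export
modal_pf_assign <- function(segments) {
  stopifnot(all(c("mt_id", "seg_index", "class_obs") %in% names(segments)))
  sp <- split(segments, segments$mt_id)
  if (any(vapply(sp, nrow, integer(1)) == 0)) stop("empty MT")
  data.frame(
    mt_id = as.integer(names(sp)),
    class = vapply(sp, function(s) modal_call(s$class_obs, s$seg_index),
                   numeric(1)),
    row.names = NULL)
}

## Circular median of phi angles (degrees): minimal-arc unwrap around a
## running estimate, then the ordinary median of the unwrapped values.
circular_median <- function(phi) {
  if (length(phi) == 1L) return(phi %% 360)
  est <- phi[1]
  unwrapped <- numeric(length(phi))
  for (i in seq_along(phi)) {
    unwrapped[i] <- est + wrap_angle(phi[i] - est)
    est <- stats::median(unwrapped[1:i])
  }
  stats::median(unwrapped) %% 360
}

#' Replace per-segment phi by the per-microtubule median
#'
#' The median-phi restraint: every segment's phi angle is replaced by its
#' microtubule's circular median, computed after removing the expected
#' skew trend (`slope`, degrees per segment; 0 by default) and restored
#' afterwards. Robust against the outlier phi assignments that survive
#' per-segment alignment.
#'
#' @param segments Segment data frame with `mt_id`, `seg_index`,
#'   `phi_obs`.
#' @param slope Expected phi trend in degrees per segment used to de-trend
#'   before the median (default 0).
#' @return `segments` with an added `phi_restrained` column (degrees in
#'   [0, 360)).
#' @export
median_phi_restraint <- function(segments, slope = 0) {
  stopifnot(all(c("mt_id", "seg_index", "phi_obs") %in% names(segments)))
  out <- segments
  out$phi_restrained <- NA_real_
  for (s in split(seq_len(nrow(segments)), segments$mt_id)) {
    detr <- segments$phi_obs[s] - slope * segments$seg_index[s]
    med <- circular_median(detr)
    out$phi_restrained[s] <- (med + slope * segments$seg_index[s]) %% 360
  }
  out
}

#' Per-microtubule seam/register vote
#'
#' Each microtubule is assigned the modal seam/register-hypothesis call of
#' its segments (hypothesis index = 2k + rho over the 2N references), with
#' the earliest-segment tie-break.
#'
#' @param segments Segment data frame with `mt_id`, `seg_index`,
#'   `hyp_obs`.
#' @return Data frame with `mt_id` and the voted `hyp` index.
#' @export
seam_vote <- function(segments) {
  stopifnot(all(c("mt_id", "seg_index", "hyp_obs") %in% names(segments)))
  sp <- split(segments, segments$mt_id)
  if (any(vapply(sp, nrow, integer(1)) == 0)) stop("empty MT")
  data.frame(
    mt_id = as.integer(names(sp)),
    hyp = vapply(sp, function(s) modal_call(s$hyp_obs, s$seg_index),
                 numeric(1)),
    row.names = NULL)
}

#' Evaluate restraint recovery against the simulation truth
#'
#' Quantifies what each per-microtubule restraint stage buys over raw
#' per-segment calls: pf-class accuracy (per segment vs per MT after the
#' modal restraint), phi error (mean absolute circular error, observed vs
#' median-restrained), and seam/register accuracy (per segment vs per MT
#' after voting), with register-only confusions (seam position k correct,
#' register rho flipped) tracked separately.
#'
#' @param segments Segment data frame as produced by
#'   [simulate_segment_dataset()] (truth columns included).
#' @param truth Per-MT truth data frame.
#' @param phi_slope Expected phi trend per segment passed to the median
#'   restraint.
#' @return Nested list with `class`, `phi` and `seam` stage summaries.
#' @export
evaluate_recovery <- function(segments, truth, phi_slope = 0) {
  cls <- modal_pf_assign(segments)
  cls_acc_seg <- mean(segments$class_obs == segments$class_true)
  cls_acc_mt <- mean(cls$class[match(truth$mt_id, cls$mt_id)] == truth$n_pf)

  res <- median_phi_restraint(segments, slope = phi_slope)
  err_obs <- mean(circ_dist(segments$phi_obs, segments$phi_true))
  err_res <- mean(circ_dist(res$phi_restrained, segments$phi_true))

  vote <- seam_vote(segments)
  hyp_acc_seg <- mean(segments$hyp_obs == segments$hyp_true)
  voted <- vote$hyp[match(truth$mt_id, vote$mt_id)]
  hyp_acc_mt <- mean(voted == truth$hyp)
  vk <- voted %/% 2; vr <- voted %% 2
  reg_only <- mean(vk == truth$hyp_k & vr != truth$hyp_rho)

  list(
    class = list(per_segment_accuracy = cls_acc_seg,
                 per_mt_accuracy = cls_acc_mt),
    phi = list(mean_abs_error_observed = err_obs,
               mean_abs_error_restrained = err_res),
    seam = list(per_segment_accuracy = hyp_acc_seg,
                per_mt_accuracy = hyp_acc_mt,
                register_only_confusion = reg_only))
}
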