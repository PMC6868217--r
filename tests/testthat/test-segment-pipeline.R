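# Per-MT restraint simulation: noise channels, modal class, median phi,
# seam voting.

test_that("zero noise reproduces truth and fixed seeds reproduce data", {
  sim <- simulate_segment_dataset(n_mt = 10, seed = 2)
  expect_equal(sim$segments$phi_obs, sim$segments$phi_true)
  expect_equal(sim$segments$class_obs, sim$segments$class_true)
  expect_equal(sim$segments$hyp_obs, sim$segments$hyp_true)
  sim2 <- simulate_segment_dataset(n_mt = 10, seed = 2)
  expect_identical(sim$segments, sim2$segments)
  sim3 <- simulate_segment_dataset(n_mt = 10, seed = 3)
  expect_false(identical(sim$segments$phi_obs, sim3$segments$phi_obs))
})

test_that("the class noise channel hits its nominal error rate", {
  sim <- simulate_segment_dataset(n_mt = 1000, n_seg = 11,
                                  class_error = 0.3, seed = 5)
  emp <- mean(sim$segments$class_obs != sim$segments$class_true)
  expect_lt(abs(emp - 0.3), 0.015)  # >= 1e4 segments, ~3 binomial SD
})

test_that("modal class: mode, tie-break, and majority-vote accuracy", {
  seg <- data.frame(mt_id = 1, seg_index = 0:3,
                    class_obs = c(13, 13, 14, 13))
  expect_equal(modal_pf_assign(seg)$class, 13)
  tie <- data.frame(mt_id = 1, seg_index = 0:3,
                    class_obs = c(14, 13, 13, 14))
  expect_equal(modal_pf_assign(tie)$class, 14)  # earliest first occurrence
  tie2 <- data.frame(mt_id = 1, seg_index = 0:3,
                     class_obs = c(13, 14, 14, 13))
  expect_equal(modal_pf_assign(tie2)$class, 13)

  sim <- simulate_segment_dataset(n_mt = 10000, n_seg = 11,
                                  class_error = 0.3, seed = 6)
  cls <- modal_pf_assign(sim$segments)
  acc <- mean(cls$class[match(sim$truth$mt_id, cls$mt_id)] ==
                sim$truth$n_pf)
  expect_gte(acc, 0.99)
})

test_that("median phi restraint is robust and improves noisy calls", {
  seg <- data.frame(mt_id = 1, seg_index = 0:8,
                    phi_obs = c(rep(40, 4), 220, rep(40, 4)))
  expect_equal(unique(median_phi_restraint(seg)$phi_restrained), 40)
  one <- data.frame(mt_id = 1, seg_index = 0, phi_obs = 123)
  expect_equal(median_phi_restraint(one)$phi_restrained, 123)
  # median respects circular wrap-around
  wrap <- data.frame(mt_id = 1, seg_index = 0:4,
                     phi_obs = c(358, 359, 0, 1, 2))
  expect_equal(mtlattice:::circ_dist(
    unique(median_phi_restraint(wrap)$phi_restrained), 0), 0,
    tolerance = 1e-9)

  sim <- simulate_segment_dataset(n_mt = 1000, n_seg = 11, phi_sd = 2,
                                  outlier_frac = 0.2, seed = 7)
  res <- median_phi_restraint(sim$segments)
  err_obs <- mean(mtlattice:::circ_dist(sim$segments$phi_obs,
                                        sim$segments$phi_true))
  err_res <- mean(mtlattice:::circ_dist(res$phi_restrained,
                                        sim$segments$phi_true))
  expect_lt(err_res, err_obs)
})

test_that("seam voting beats per-segment hypothesis calls", {
  sim <- simulate_segment_dataset(n_mt = 2000, n_seg = 11,
                                  hyp_error = 0.4, seed = 8)
  vote <- seam_vote(sim$segments)
  acc_seg <- mean(sim$segments$hyp_obs == sim$segments$hyp_true)
  acc_mt <- mean(vote$hyp[match(sim$truth$mt_id, vote$mt_id)] ==
                   sim$truth$hyp)
  expect_gt(acc_mt, acc_seg)
  expect_gt(acc_mt, 0.95)
  unan <- data.frame(mt_id = 1, seg_index = 0:4, hyp_obs = rep(17, 5))
  expect_equal(seam_vote(unan)$hyp, 17)
})

test_that("restraints reduce error at three noise levels", {
  for (lvl in list(c(phi = 1, cls = 0.1, hyp = 0.2),
                   c(phi = 2, cls = 0.3, hyp = 0.4),
                   c(phi = 4, cls = 0.5, hyp = 0.6))) {
    sim <- simulate_segment_dataset(n_mt = 1000, n_seg = 11,
                                    phi_sd = lvl["phi"],
                                    outlier_frac = 0.1,
                                    class_error = lvl["cls"],
                                    hyp_error = lvl["hyp"],
                                    seed = 100 + round(10 * lvl["phi"]))
    rec <- evaluate_recovery(sim$segments, sim$truth)
    expect_gt(rec$class$per_mt_accuracy, rec$class$per_segment_accuracy)
    expect_lt(rec$phi$mean_abs_error_restrained,
              rec$phi$mean_abs_error_observed)
    expect_gt(rec$seam$per_mt_accuracy, rec$seam$per_segment_accuracy)
    expect_gte(rec$seam$register_only_confusion, 0)
  }
})

test_that("restraints are per-MT pure: permuting MTs permutes outputs", {
  sim <- simulate_segment_dataset(n_mt = 20, n_seg = 5, phi_sd = 3,
                                  class_error = 0.2, seed = 12)
  seg <- sim$segments
  perm <- seg[order(-seg$mt_id, seg$seg_index), ]
  a <- modal_pf_assign(seg); b <- modal_pf_assign(perm)
  expect_equal(a[order(a$mt_id), ], b[order(b$mt_id), ])
  ra <- median_phi_restraint(seg); rb <- median_phi_restraint(perm)
  key <- function(d) paste(d$mt_id, d$seg_index)
  expect_equal(ra$phi_restrained,
               rb$phi_restrained[match(key(ra), key(rb))])
})
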