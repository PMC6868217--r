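# Rigid superposition, anchored RMSD profiles and tilt/stagger
# classification.

test_that("superposition recovers exact rigid motions", {
  set.seed(3)
  pts <- matrix(rnorm(30), ncol = 3)
  fit0 <- superpose_rigid(pts, pts)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  R <- mtlattice:::rotation_z(10)
  moved <- sweep(pts %*% t(R), 2, c(5, -2, 7), "+")
  fit <- superpose_rigid(pts, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  ang <- acos((sum(diag(fit$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 10, tolerance = 1e-6)
})

test_that("superposition matches the brute-force rotation-grid oracle", {
  set.seed(8)
  for (i in 1:3) {
    n <- sample(5:10, 1)
    pts <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    moved <- pts %*% t(mtlattice:::rotation_z(runif(1, 0, 360))) +
      matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
    fit <- superpose_rigid(pts, moved)
    oracle <- grid_superpose_z(pts, moved, step = 0.1)
    expect_lte(fit$rmsd, oracle + 1e-3)  # optimal <= any grid candidate
    expect_gt(fit$rmsd, oracle * 0.95 - 1e-3)
  }
  # larger noisy cloud: residual close to the noise-model expectation
  pts <- matrix(rnorm(150, sd = 10), ncol = 3)
  noisy <- pts + matrix(rnorm(150, sd = 0.1), ncol = 3)
  fit <- superpose_rigid(pts, noisy)
  expect_equal(fit$rmsd, 0.1 * sqrt(3), tolerance = 0.35)
})

test_that("superposition residual agrees with an independent library fit", {
  set.seed(14)
  pts <- matrix(rnorm(90, sd = 5), ncol = 3)
  R <- mtlattice:::rotation_about_axis(c(1, 1, 2), 25)
  target <- sweep(pts %*% t(R), 2, c(3, -1, 4), "+") +
    matrix(rnorm(90, sd = 0.2), ncol = 3)
  ours <- superpose_rigid(pts, target)
  moved <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(target)),
                   mobile = as.numeric(t(pts))))
  ref_rmsd <- sqrt(mean(colSums(
    (matrix(moved, nrow = 3) - t(target))^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose_rigid(line, line), "collinear|degenerate")
  expect_error(superpose_rigid(matrix(0, 2, 3), matrix(0, 2, 3)), ">= 3")
})

test_that("identical lattices give all-zero profiles in both modes", {
  lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 4))
  g <- rmsd_profile(lat, lat, "global_anchor")
  p <- rmsd_profile(lat, lat, "per_pf")
  expect_equal(unname(g$values), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(p$values), rep(0, 4), tolerance = 1e-9)
  expect_equal(g$anchor_rmsd, 0, tolerance = 1e-9)
})

test_that("tilt pairs grow globally but stay rigid per protofilament", {
  ref <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6))
  tilt <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6,
                                     skew_mode = "by_dphi",
                                     skew_value = 0.25,
                                     mechanism = "tilt"))
  g <- rmsd_profile(ref, tilt, "global_anchor")
  p <- rmsd_profile(ref, tilt, "per_pf")
  expect_equal(g$anchor_rmsd, 0, tolerance = 0.02)
  # divergence increases away from the anchor
  expect_gt(g$values[6], g$values[1])
  expect_true(all(diff(g$values[2:6]) > 0))
  # whole protofilaments are internally unchanged: < 1 A everywhere
  expect_true(all(p$values < 1))
  expect_true(all(p$values < 0.1))
})

test_that("stagger pairs shear protofilaments internally", {
  ref <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6))
  stag <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6,
                                     skew_mode = "by_dphi",
                                     skew_value = 0.25,
                                     mechanism = "stagger"))
  p <- rmsd_profile(ref, stag, "per_pf")
  expect_true(all(diff(p$values) > 0))  # grows with axial distance
  expect_gt(p$values[6], 1)
})

test_that("profiles demand matching topology", {
  a <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 4))
  b <- build_lattice(lattice_spec(n_pf = 14, n_dimers = 4))
  expect_error(rmsd_profile(a, b), "topology")
})

test_that("mechanism classification is exact on noise-free pairs", {
  for (N in c(13, 14)) {
    ref <- build_lattice(lattice_spec(n_pf = N, n_dimers = 6))
    for (dphi in c(0.05, 0.15, 0.5)) {
      for (mech in c("tilt", "stagger")) {
        lat <- build_lattice(lattice_spec(
          n_pf = N, n_dimers = 6, skew_mode = "by_dphi",
          skew_value = dphi, mechanism = mech))
        cl <- classify_mechanism(rmsd_profile(ref, lat, "global_anchor"),
                                 rmsd_profile(ref, lat, "per_pf"))
        expect_equal(cl$mechanism, mech,
                     label = sprintf("N=%d dphi=%.2f %s -> %s",
                                     N, dphi, mech, cl$mechanism))
      }
    }
    cl0 <- classify_mechanism(rmsd_profile(ref, ref, "global_anchor"),
                              rmsd_profile(ref, ref, "per_pf"))
    expect_equal(cl0$mechanism, "none")
  }
})

test_that("body tilt tracks the skew angle under tilt but not stagger", {
  ref <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 4))
  expect_equal(body_tilt(ref)$mean_tilt, 0, tolerance = 1e-9)
  for (dphi in c(0.2, -0.3)) {
    tilt <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 4,
                                       skew_mode = "by_dphi",
                                       skew_value = dphi,
                                       mechanism = "tilt"))
    theta <- accommodation_solve(tilt$spec)$theta
    expect_equal(body_tilt(tilt)$mean_tilt, theta, tolerance = 1e-6)
    stag <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 4,
                                       skew_mode = "by_dphi",
                                       skew_value = dphi,
                                       mechanism = "stagger"))
    expect_equal(body_tilt(stag)$mean_tilt, 0, tolerance = 1e-9)
  }
})

test_that("measure_skew reads back the generated rotation per dimer", {
  for (dphi in c(0, 0.25, -0.5)) {
    lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6,
                                      skew_mode = "by_dphi",
                                      skew_value = dphi,
                                      mechanism = "tilt"))
    expect_equal(measure_skew(lat)$dphi_per_dimer, dphi,
                 tolerance = 1e-6)
  }
})

test_that("estimator-based classification is exact on noise-free pairs", {
  ref <- build_lattice(lattice_spec(n_pf = 14, n_dimers = 6))
  expect_equal(classify_skew_mechanism(ref, ref)$mechanism, "none")
  for (mech in c("tilt", "stagger")) {
    lat <- build_lattice(lattice_spec(n_pf = 14, n_dimers = 6,
                                      skew_mode = "by_dphi",
                                      skew_value = 0.3,
                                      mechanism = mech))
    cl <- classify_skew_mechanism(ref, lat)
    expect_equal(cl$mechanism, mech)
    expect_gte(cl$confidence, 0.9)
  }
})

test_that("classification is invariant to global rigid motion", {
  ref <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6))
  tilt <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6,
                                     skew_mode = "by_dphi",
                                     skew_value = 0.2,
                                     mechanism = "tilt"))
  moved <- rigid_move(tilt, angle = 71, shift = c(-30, 80, 15))
  cl <- classify_mechanism(rmsd_profile(ref, moved, "global_anchor"),
                           rmsd_profile(ref, moved, "per_pf"))
  expect_equal(cl$mechanism, "tilt")
})
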