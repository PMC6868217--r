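# NMR metrics: CSP combination, CPMG flatness, CEST dip scan, assignment
# transfer and completeness.

test_that("csp evaluates the combined-shift formula exactly", {
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.3, 2.0), sqrt(0.09 + 0.09), tolerance = 1e-9)
  expect_equal(csp(0.1, 1.0), sqrt(0.01 + 0.0225), tolerance = 1e-9)
})

test_that("csp is non-negative, sign-symmetric and 1-homogeneous", {
  set.seed(4)
  dH <- rnorm(50); dN <- rnorm(50)
  v <- csp(dH, dN)
  expect_true(all(v >= 0))
  expect_equal(csp(-dH, dN), v)
  expect_equal(csp(dH, -dN), v)
  expect_equal(csp(3 * dH, 3 * dN), 3 * v, tolerance = 1e-12)
  expect_true(all((v == 0) == (dH == 0 & dN == 0)))
})

test_that("cpmg flatness is SD/mean, scale-invariant, and errors sanely", {
  expect_equal(cpmg_flatness(rep(100, 10)), 0)
  x <- c(95, 105, 95, 105)  # sd 5.7735 about mean 100
  expect_equal(cpmg_flatness(x), sd(x) / 100, tolerance = 1e-12)
  expect_equal(cpmg_flatness(10 * x), cpmg_flatness(x), tolerance = 1e-12)
  expect_error(cpmg_flatness(5), ">= 2")
  expect_error(cpmg_flatness(c(-1, 1)), "zero")
})

test_that("hand-built SD-about-mean example gives the expected ratio", {
  # intensities engineered to sd 5, mean 100
  x <- 100 + 5 * scale(rnorm(15))[, 1]
  expect_equal(cpmg_flatness(x), 0.05, tolerance = 1e-9)
})

test_that("two-state exchange raises the dispersion ratio above the null", {
  flat <- simulate_cpmg_series(dw = 0, noise_sd = 0.5, seed = 10)
  exch <- simulate_cpmg_series(dw = 300, kex = 800, pa = 0.95,
                               noise_sd = 0.5, seed = 10)
  expect_gt(cpmg_flatness(exch$intensity),
            3 * cpmg_flatness(flat$intensity))
  # the simulated fields are the experiment's 15 CPMG frequencies
  expect_length(cpmg_fields(), 15)
  expect_equal(range(cpmg_fields()), c(50, 1500))
})

test_that("cest dip scan finds injected minor dips and only those", {
  clean <- simulate_cest_profile(noise_sd = 0.01, seed = 1)
  expect_equal(nrow(cest_dip_scan(clean, 0.01)), 0)

  inj <- simulate_cest_profile(minor_offset = 7000,
                               minor_depth = 5 * 0.01,
                               noise_sd = 0.01, seed = 2)
  dips <- cest_dip_scan(inj, 0.01)
  expect_gte(nrow(dips), 1)
  expect_lte(min(abs(dips$offset_hz - 7000)), 25)  # within one spacing
  expect_error(cest_dip_scan(clean[1:4, ], 0.01), ">= 5")
})

test_that("all-noise profiles false-positive at most at the 3-sigma rate", {
  set.seed(30)
  n_prof <- 300
  offs <- cest_offsets()
  hits <- 0
  for (i in seq_len(n_prof)) {
    prof <- data.frame(offset_hz = offs,
                       intensity = 1 + rnorm(length(offs), 0, 0.01))
    if (nrow(cest_dip_scan(prof, 0.01)) > 0) hits <- hits + 1
  }
  # per-point one-sided 3-sigma tail, any of the points (conservative:
  # the scan also removes the deepest run as the "main" dip)
  p_point <- pnorm(-3)
  p_any <- 1 - (1 - p_point)^length(offs)
  bound <- p_any + 3 * sqrt(p_any * (1 - p_any) / n_prof)
  expect_lte(hits / n_prof, bound)
})

test_that("assignment transfer honours the per-dimension tolerances", {
  sol <- data.frame(residue_id = 1:5, HN = seq(7, 9, 0.5),
                    N = seq(110, 130, 5), CA = seq(50, 60, 2.5))
  obs <- sol; obs$peak_id <- obs$residue_id
  tr <- transfer_assignments(sol, obs)
  expect_equal(nrow(tr$matches), 5)
  expect_equal(max(tr$matches$dist), 0)
  expect_equal(tr$matches$peak_id, tr$matches$residue_id)

  # displacement by twice the HN tolerance breaks the match
  obs2 <- obs; obs2$HN[3] <- obs2$HN[3] + 0.2
  tr2 <- transfer_assignments(sol, obs2)
  expect_true(3 %in% tr2$unmatched_solution)
  expect_equal(nrow(tr2$matches), 4)
})

test_that("greedy transfer equals the exhaustive oracle on small tables", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    sol <- data.frame(residue_id = seq_len(n),
                      HN = runif(n, 7, 9.5), N = runif(n, 105, 130),
                      CA = runif(n, 45, 65))
    obs <- sol
    keep <- runif(n) > 0.1  # ~10% missing peaks
    obs <- obs[keep, , drop = FALSE]
    obs$HN <- obs$HN + rnorm(nrow(obs), 0, 0.1 / 2)
    obs$N <- obs$N + rnorm(nrow(obs), 0, 0.6 / 2)
    obs$CA <- obs$CA + rnorm(nrow(obs), 0, 0.5 / 2)
    obs$peak_id <- obs$residue_id
    tr <- transfer_assignments(sol, obs)
    oracle <- optimal_transfer(sol, obs)
    expect_equal(nrow(tr$matches), max(oracle$n, 0))
    if (oracle$n > 0)
      expect_equal(sum(tr$matches$dist), oracle$dist, tolerance = 1e-9)
  }
})

test_that("assignment completeness reproduces the construct percentages", {
  # 124 assigned over residues 1474..1613 (140 residues)
  expect_equal(assignment_completeness(1474:1597, 1474:1613),
               100 * 124 / 140, tolerance = 1e-12)
  expect_equal(round(assignment_completeness(1474:1597, 1474:1613), 1),
               88.6)
  # 87 assigned over residues 621..788 (168 residues)
  expect_equal(round(assignment_completeness(621:707, 621:788), 1), 51.8)
  expect_equal(assignment_completeness(1:10, 1:10), 100)
  expect_error(assignment_completeness(1:5, integer(0)), "empty")
})
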