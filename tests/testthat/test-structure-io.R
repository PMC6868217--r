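# Coordinate I/O, contact footprint, region RMSD.

test_that("lattice PDB round-trip preserves topology and coordinates", {
  lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 2))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_lattice_pdb(lat, tf)
  model <- read_model(tf)
  expect_s3_class(model, "structure_model")
  expect_equal(length(unique(model$atoms$chain)), 13)
  lat2 <- lattice_from_model(model, spec = lat$spec)
  expect_equal(as.matrix(lat2$atoms[, c("x", "y", "z")]),
               as.matrix(lat$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3)
  expect_equal(measure_diameter(lat2)$diameter,
               measure_diameter(lat)$diameter, tolerance = 1e-2)
})

test_that("missing files and malformed records are reported", {
  expect_error(read_model("no-such-file.pdb"), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM  mangled record that is not fixed-width"), bad)
  expect_error(read_model(bad), "malformed|PDB")
})

test_that("insertion codes are parsed, never silently dropped", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  10      11.000  12.000  13.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A  10A     14.000  15.000  16.000  1.00  0.00           C",
    "END"), tf)
  model <- read_model(tf)
  expect_equal(nrow(model$atoms), 2)
  expect_setequal(model$atoms$insert, c("", "A"))
})

test_that("chain roles come from vectors or JSON sidecars", {
  lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 1))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_lattice_pdb(lat, tf)
  m1 <- read_model(tf, chain_roles = c(A = "alpha1", B = "beta1"))
  expect_equal(unname(m1$chain_roles[c("A", "B")]),
               c("alpha1", "beta1"))
  side <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(A = "CKK"), side, auto_unbox = TRUE)
  m2 <- read_model(tf, chain_roles = side)
  expect_equal(unname(m2$chain_roles["A"]), "CKK")
  expect_error(contact_footprint(read_model(tf)), "roles")
})

test_that("contact footprint applies the cutoff inclusively", {
  mk <- function(d) {
    atoms <- data.frame(
      chain = c("K", "A"), resno = c(1, 1), insert = "",
      resid = c("CKK", "TUB"), elety = "CA",
      x = c(0, d), y = 0, z = 0)
    structure(list(atoms = atoms,
                   chain_roles = c(K = "CKK", A = "alpha1"),
                   source = "synthetic"),
              class = "structure_model")
  }
  expect_equal(contact_footprint(mk(4.9))$counts[["alpha1"]], 1)
  expect_equal(contact_footprint(mk(5.0))$counts[["alpha1"]], 1)
  expect_equal(contact_footprint(mk(5.1))$counts[["alpha1"]], 0)
  expect_equal(sum(contact_footprint(mk(0.5), cutoff = 0)$counts), 0)
})

test_that("a CKK wedged at a junction touches exactly the four subunits", {
  lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 2))
  model <- synthetic_site_model(lat, junction = 3, reach = 4.9)
  fp <- contact_footprint(model, cutoff = 5)
  expect_setequal(names(fp$counts),
                  c("alpha1", "beta1", "alpha2", "beta2"))
  expect_true(all(fp$counts >= 1))
  # a tighter cutoff than the reach excludes everything
  fp2 <- contact_footprint(model, cutoff = 2)
  expect_equal(sum(fp2$counts), 0)
})

test_that("footprint is invariant to global rigid motion", {
  lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 2))
  model <- synthetic_site_model(lat, junction = 5, reach = 4.5)
  R <- mtlattice:::rotation_about_axis(c(2, 1, 1), 57)
  moved <- model
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  moved$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(11, -7, 3), "+")
  expect_equal(contact_footprint(moved, 5)$counts,
               contact_footprint(model, 5)$counts)
})

test_that("region RMSD reads back an injected displacement", {
  mA <- synthetic_protein_model(n_res = 30, seed = 2)
  expect_equal(as.numeric(region_rmsd(mA, mA, "A:1-30",
                                      c(all = "A:1-30"))), 0,
               tolerance = 1e-12)
  mB <- mA
  sel <- mB$atoms$resno >= 20 & mB$atoms$resno <= 25
  mB$atoms$y[sel] <- mB$atoms$y[sel] + 3
  rr <- region_rmsd(mA, mB, core_selection = "A:1-15",
                    region_selections = c(loop = "A:20-25",
                                          core2 = "A:5-12"))
  expect_equal(unname(rr["loop"]), 3, tolerance = 0.05)
  expect_lt(rr["core2"], 0.05)
  expect_error(region_rmsd(mA, mB, "B:1-10", c(x = "A:1-5")),
               "empty correspondence")
  expect_error(mtlattice:::parse_selection("A1-30"), "selection")
})

test_that("region RMSD satisfies a triangle-inequality sanity check", {
  mA <- synthetic_protein_model(n_res = 20, seed = 5)
  perturbed <- function(sd, seed) {
    m <- mA
    set.seed(seed)
    m$atoms$x <- m$atoms$x + rnorm(nrow(m$atoms), 0, sd)
    m
  }
  mB <- perturbed(0.3, 6); mC <- perturbed(0.6, 7)
  reg <- c(all = "A:1-20")
  ab <- region_rmsd(mA, mB, "A:1-20", reg)["all"]
  bc <- region_rmsd(mB, mC, "A:1-20", reg)["all"]
  ac <- region_rmsd(mA, mC, "A:1-20", reg)["all"]
  expect_lte(ac, ab + bc + 1e-9)
})
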