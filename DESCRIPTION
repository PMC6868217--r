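Package: mtlattice
Title: Microtubule Lattice Geometry, Protofilament Skew Decomposition
    and CKK Binding-Site Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how microtubule-associated proteins
    remodel the microtubule lattice, motivated by the CAMSAP/Patronin CKK
    domain. Generates synthetic pseudo-helical B-lattice microtubules with
    a single seam under the lattice accommodation closure (protofilament
    number, 3-start rise, skew angle and rotation-per-dimer are mutually
    constrained); measures diameter, adjacent-dimer centre-of-mass
    separations, interprotofilament lateral angles and per-dimer skew;
    decomposes protofilament skew into whole-protofilament tilt versus
    interdimer stagger from anchored RMSD profiles; enumerates the 2N
    seam-position/register hypotheses of pseudo-helical processing and the
    CKK binding sites they imply; simulates per-microtubule segment
    restraints (modal protofilament class, median phi, seam voting); and
    implements the NMR metrics used to establish CKK domain rigidity
    (combined chemical-shift perturbation, CPMG dispersion flatness, CEST
    dip scanning, assignment transfer by spectral proximity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
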