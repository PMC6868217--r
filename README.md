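# mtlattice

Quantitative geometry of microtubule lattice remodelling by
microtubule-associated proteins, built around the CAMSAP/Patronin CKK
domain. CKK domains bind between two tubulin dimers on adjacent
protofilaments; the minus-end-recognising human ortholog remodels its
binding site — inducing right-handed protofilament skew, contracting the
microtubule diameter and pulling adjacent dimers closer — while
non-recognising orthologs leave the lattice untouched. `mtlattice`
provides the synthetic lattices, measurements and statistics needed to
make those statements quantitative and testable on a desk.

## What it computes

The microtubule wall is a pseudo-helical B-lattice of N protofilaments
with one A-lattice seam, constrained by the **lattice accommodation
closure**

    tan(theta) = (S*a − N*h) / (2*pi*r)
    dPHI_per_dimer = (2*a*tan(theta)/r) * (180/pi)

linking start number S, monomer repeat a, lateral rise h, radius r and
protofilament skew angle theta (positive = right-handed). On top of this
model the package implements:

- **`lattice_synth`** — `lattice_spec()` / `build_lattice()` /
  `perturb_lattice()`: synthetic lattices with configurable N, seam
  position, alpha/beta register, skew (by theta, rise or dPHI), two skew
  mechanisms (whole-protofilament **tilt** vs interdimer **stagger**,
  realized on 5-atom rigid monomer bodies), asymmetric radial offsets,
  lateral compression, coordinate noise, all seeded.
- **geometry** — diameter and per-protofilament radii about a fitted
  cylinder axis, adjacent B-lattice dimer COM separations along one
  3-start turn, interprotofilament lateral angles (360/13 − 360/14 ≈
  1.98°), and the per-microtubule rotation-per-dimer skew statistic
  fitted from segment phi series.
- **decomposition** — Kabsch superposition, anchored RMSD profiles
  (global vs per-protofilament), and two classifiers for tilt / stagger
  / none: the profile-based rule and a noise-robust estimator comparing
  measured body tilt with the closure-implied skew angle.
- **`seam_registry`** — the 2N seam-position/register hypotheses of
  pseudo-helical processing (26 for N = 13) as explicit rigid
  transforms, plus CKK binding-site enumeration (one site per non-seam
  junction per ring, 8 nm apart, none at the seam).
- **`segment_pipeline`** — Monte-Carlo simulation of per-microtubule
  restraints: modal protofilament class, circular-median phi, seam
  voting, with recovery evaluation against ground truth.
- **`nmr_metrics`** — combined chemical-shift perturbation
  sqrt((0.15·ΔN)² + ΔH²), CPMG dispersion flatness (SD/mean across
  50–1500 Hz fields), CEST minor-dip scanning, assignment transfer by
  HN/N/CA spectral proximity, assignment completeness.
- **`structure_io`** — PDB/mmCIF models via `bio3d`, synthetic-lattice
  PDB export/import, 5 Å contact footprints per tubulin subunit, and
  per-region backbone RMSD after core superposition.

## Worked example

Contract a 13-protofilament lattice radially by 2 Å per protofilament,
then separately compress its lateral dimer spacing by 0.4 Å, and measure
both against the unperturbed reference:

```r
library(mtlattice)

ref <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6))

compare_lattices(ref, perturb_lattice(ref, pf_radial_offsets = rep(-2, 13)))
#> Lattice comparison (reference - test):
#>   diameter difference: 4.000 A
#>   adjacent-dimer COM separation: 0.940 +/- 0.000 A over 12 junctions
#>   lateral angle difference: -0.000 deg

compare_lattices(ref, perturb_lattice(ref, lateral_compression = 0.4))
#> Lattice comparison (reference - test):
#>   diameter difference: 1.701 A
#>   adjacent-dimer COM separation: 0.400 +/- 0.000 A over 12 junctions
#>   lateral angle difference: -0.000 deg
```

The first comparison reads back the injected 2 Å offsets as a 4 Å
diameter contraction; the second shows the exact 0.4 Å separation
compression (which itself implies a ~1.7 Å diameter change — the two
remodelling modes are geometrically coupled). Mechanism classification
on a right-handed 0.25°/dimer skew realized by whole-protofilament tilt:

```r
tilt <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 6,
                                   skew_mode = "by_dphi",
                                   skew_value = 0.25, mechanism = "tilt"))
classify_skew_mechanism(ref, tilt)
#> $mechanism   [1] "tilt"
#> $confidence  [1] 1
#> $dphi_diff   [1] 0.25        # deg/dimer, as injected
#> $body_tilt_diff [1] 0.32     # deg — matches theta_expected
#> $theta_expected [1] 0.32
```

The bodies lean by exactly the closure-implied 0.32°, so the skew comes
from tilting whole protofilaments, not from interdimer stagger.

## Analysis workflow

Numbered drivers under `analysis/` run the full study over the package
and write tables under `results/` (each with a `config.json` capturing
parameters and seed):

```sh
Rscript analysis/01_build_lattices.R    --seed 1   # lattice panel + PDBs
Rscript analysis/02_lattice_geometry.R  --seed 1   # diameters, separations, angles
Rscript analysis/03_skew_decomposition.R --seed 1  # RMSD profiles, tilt/stagger
Rscript analysis/04_seam_registry.R     --seed 1   # 2N hypothesis grid, CKK sites
Rscript analysis/05_segment_restraints.R --seed 1  # modal/median/vote recovery
Rscript analysis/06_nmr_metrics.R       --seed 1   # CSP, CPMG, CEST, transfer
```

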