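---
title: "Microtubule lattice remodelling: models, measurements and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microtubule lattice remodelling: models, measurements and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlattice)
```

`mtlattice` quantifies how a microtubule-binding protein remodels the
microtubule wall, motivated by the CAMSAP/Patronin CKK domain: a small,
rigid domain that binds between two tubulin dimers on adjacent
protofilaments and — in its minus-end-recognising orthologs — induces a
right-handed protofilament skew, a diameter contraction and a lateral
compression of its binding site. This vignette explains the geometric
model behind the package, what each measurement estimates, where the
numerical choices come from, and what the synthetic data can and cannot
say about real cryo-EM-derived models.

## The pseudo-helical lattice model

A microtubule is modelled as N protofilaments (8–17; most commonly 13 or
14) of alpha/beta-tubulin dimers with monomer repeat *a* (default 41 Å,
dimer repeat 82 Å) at radius *r* from the axis (default 105 Å). Lateral
monomer contacts form an S-start helix (S = 3 canonically): going once
around the wall climbs S monomers. Because S is odd while the dimer is
two monomers, a B-lattice wall (alpha beside alpha) cannot close
seamlessly: exactly one junction — the seam — makes A-lattice contacts
(alpha beside beta). The generator realizes this directly: protofilament
k is assigned helical order m = (k − seam_index − 1) mod N and axial
offset m·h, so the wrap junction, and with it the seam, sits at the
requested junction index.

The **lattice accommodation closure** couples the free parameters:

$$\tan\theta = \frac{S a - N h}{2 \pi r}, \qquad
  \Delta\Phi_{\text{dimer}} = \frac{2 a \tan\theta}{r}\cdot\frac{180}{\pi}$$

where θ is the protofilament skew angle, h the lateral monomer rise and
ΔΦ the rotation about the axis per dimer step along a protofilament.
Exactly one of θ / h / ΔΦ is free in a `lattice_spec()`; the other two
follow. Sign convention: the axis **+z** points to the plus end, azimuth
is right-handed about +z, and positive θ / ΔΦ means right-handed skew —
so a 13-protofilament, 3-start lattice with θ = 0 has h = 3·41/13 ≈
9.46 Å, and a 14-protofilament lattice holding that same rise solves to
θ ≈ −0.82° (left-handed), ΔΦ ≈ −0.64°/dimer — the intrinsic supertwist
of 14-protofilament microtubules.

```{r closure}
accommodation_solve(lattice_spec(n_pf = 14, skew_mode = "by_rise",
                                 skew_value = 3 * 41 / 13))
```

**Monomers are 5-atom rigid bodies, not points.** Each monomer carries
five labelled pseudo-atoms spanning ~20 Å in a fixed chiral template.
This is the smallest representation on which the two skew mechanisms are
distinguishable: *tilt* rotates every body about its radial axis by θ
(the protofilament remains a straight, tilted rod), while *stagger*
keeps bodies axis-aligned and offsets successive dimers tangentially by
the same per-dimer increment (the protofilament is internally sheared).
On centre points alone the two produce identical coordinates.

**Perturbations** model the binding-site remodelling: per-protofilament
radial offsets (the asymmetric 0.4–1.5 Å inward shifts), a lateral
compression applied as the exact uniform radial contraction that reduces
the adjacent-dimer centre-of-mass separation by the requested amount,
and isotropic Gaussian coordinate noise. All randomness flows from one
integer seed; a spec plus seed reproduces coordinates bitwise.

## Measurements

- `measure_diameter()`: twice the mean radial distance of dimer COMs to
  a least-squares cylinder axis. The default radius is a package choice
  (the monomer reference point of a real model is not comparable), so
  **only differences** between lattices measured the same way are
  meaningful; `compare_lattices()` therefore measures both lattices
  about the *reference's* axis. This also matters statistically: a
  first-harmonic pattern of radial offsets is partly degenerate with an
  axis translation, so per-protofilament offsets are only exactly
  recoverable against a common axis.
- `adjacent_dimer_separations()`: Euclidean COM distances along one
  complete lateral turn (one dimer per protofilament in helical order at
  a common level), seam junction excluded by default since the reference
  quantity concerns B-lattice pairs. For an ideal lattice each
  separation is √(chord² + h²) with chord = 2r·sin(π/N).
- `lateral_angle()`: mean angle subtended at the axis between adjacent
  protofilament centre lines; 360/N for ideal lattices, hence the
  1.98° difference between 13- and 14-protofilament architectures.
- `fit_phi_slope()`: the per-microtubule skew statistic used on segment
  alignment angles — unwrap phi into (−180/N, +180/N] steps, fit phi
  against dimer index per microtubule, aggregate mean ± SD.

## Tilt versus stagger

`rmsd_profile()` compares two lattices of identical topology under two
alignments. Anchored globally (whole lattice superposed on the bottom
anchor dimer), any skew difference makes the profile grow with axial
distance. Superposing each protofilament pair independently on its own
bottom dimer collapses the divergence only if protofilaments are
internally identical rigid rods: under tilt the per-protofilament
profile stays flat and far below 1 Å; under stagger it keeps growing.
`classify_mechanism()` encodes this with a flatness threshold (0.25 Å
excess drift), the per-protofilament bound (1.0 Å, following the
reported sub-Ångström per-protofilament residuals) and — the package's
own refinement — the *growth-rate ratio* of the squared profiles
(tilt ≈ 0, stagger ≈ 1, decision at 0.5). The ratio keeps the decision
scale-free: with an absolute bound alone, a small stagger (0.05°/dimer
shears a 6-dimer protofilament by only ~0.3 Å) would be mislabelled as
tilt.

**Noise changes the picture qualitatively.** The anchor dimer offers 10
atoms lying nearly along a line, so on noisy coordinates its
superposition has a poorly determined rotation dof whose error grows
linearly along the lattice — indistinguishable in shape from a genuine
stagger ramp; conversely, widening the anchor absorbs the stagger ramp
itself (a rotation cancels a linear tangential drift exactly). No
anchored-profile variant separates the mechanisms robustly at 0.3 Å
coordinate noise. `classify_skew_mechanism()` therefore estimates the
two physically defining quantities directly: the skew difference from
dimer-COM azimuth slopes, and the mean tangential **body tilt** from
per-monomer template fits, compared with the θ implied by the measured
skew under the closure. Both statistics average over every monomer, so
their errors shrink with lattice size; on noise-free pairs the decision
is exact. Thresholds: skew differences below 0.02°/dimer (several
standard errors of the slope estimate at 0.3 Å noise, and far below any
measurable supertwist) are "none"; the body-tilt-to-θ ratio separates
stagger (≈0) from tilt (≈1) at 0.5. For noisy classification the
analysis averages 7 replicate realizations first — the synthetic
analogue of the 7-segment averages a pseudo-helical reconstruction
pipeline feeds into 3D classification.

## Seam/register hypotheses and binding sites

A pseudo-helical reconstruction must decide where the seam is and which
alpha/beta register the decoration has: 2N hypotheses (26 for N = 13),
each the rigid transform composing the helical operator k times
(rotation k·360/N, rise k·h) with an optional one-monomer (+a) register
shift. For any valid spec the 2N transforms are provably distinct; the
enumeration still deduplicates by transform equality (1e-6 tolerance)
and warns, per contract, should degenerate parameters ever collapse two.
CKK binding sites sit at the midpoint of laterally adjacent dimer COMs —
one site per non-seam junction per ring (N − 1 per ring), 82 Å ≈ 8 nm
apart along the axis, none at the seam.

## Segment restraints

The per-microtubule restraint logic of the processing pipeline is
simulated as a categorical/Gaussian observation model per 82 Å segment:
phi plus Gaussian noise with a uniform-outlier fraction, and class /
hypothesis calls correct with stated probability, else uniform over the
alternatives. This deliberately skips all density-space computation: it
is the restraint logic, not the classifier, that is under test. Modal
protofilament class, circular-median phi (minimal-arc unwrap around a
running estimate; de-trended by an expected slope when supplied, default
0) and modal seam voting each replace per-segment calls by per-MT
consensus; ties break toward the class whose earliest segment occurs
first, which makes reruns deterministic. With 11 segments per
microtubule, a 30% per-segment class error still yields >99% per-MT
accuracy — the binomial arithmetic behind restraining everything per
microtubule.

## NMR metrics

Chemical-shift perturbations combine as √((0.15·ΔN)² + ΔH²) (ppm).
CPMG dispersion flatness is the SD/mean ratio of peak intensities across
the 15 refocusing fields (50–1500 Hz, constant 40 ms relaxation time); a
rigid residue's profile is flat, and the synthetic oracle generates
two-state fast-exchange profiles with the Luz–Meiboom expression. CEST
profiles (offsets 8200→6325 Hz, 25 Hz spacing) are scanned for dips
deeper than 3× the noise SD below the median baseline, excluding the
main-resonance dip. Assignment transfer assumes spectral proximity in
HN/N/CA with per-dimension tolerances set to the determined linewidths
(0.1 ppm ¹H, 0.6 ppm ¹⁵N); CA is not printed anywhere, so its tolerance
defaults to 0.5 ppm and is configurable. Matching is greedy
mutual-nearest in tolerance-scaled space — transparent, and verified
equal to exhaustive optimal assignment on small instances.
`assignment_completeness()` returns the exact percentage
(100·|assigned ∩ range|/|range|); rounding is left to the caller, since
printed percentages (88%, 52%) depend on unstated rounding conventions.

```{r nmr}
csp(0.3, 2.0)
assignment_completeness(seq_len(124) + 1473, 1474:1613)
```

## Problem sizes and determinism

Analysis and test runs use lattices of 4–6 dimer rings (520–780
pseudo-atoms for N = 13), 200 replicates for recovery studies, and 10³
microtubules (11 segments each) for restraint Monte Carlo — sizes at
which every recovery statistic is stable to well under its standard
error and a full run completes in minutes on one core. Every stochastic
stage takes an explicit integer seed; drivers write their configuration
as JSON next to their outputs so each artifact is reproducible from
config plus seed.

## What the synthetic data do and do not show

The generator reproduces the *geometry* of decorated-microtubule
lattices: closure-consistent skew, a single seam, both accommodation
mechanisms, asymmetric radial remodelling, and segment-level observation
noise with outliers. It does not emulate cryo-EM densities, the
resolution gradient of real reconstructions, atomistic tubulin
conformations, or nucleotide-state lattice compaction. Passing tests
therefore demonstrate that the *measurements and restraint logic* are
correct and unbiased on data whose ground truth is known — not that any
specific biological value (e.g. an absolute diameter) is reproduced.
Deposited coordinate models can be loaded through `read_model()` and
measured with the same operators (`region_rmsd()`,
`contact_footprint()`, `lattice_from_model()`); the contact footprint is
a 5 Å any-atom distance criterion (inclusive, matching the "< 5 Å"
colouring convention) and yields contact-residue counts, deliberately
not buried-surface areas. Divergent-loop selections for real CKK models
must be user-supplied, since the loop boundaries are defined only in
supplementary material of the underlying structures.

## Known limitations

- Absolute diameters and separations depend on the package's default
  COM radius; only within-package differences are comparable to
  reported differences.
- `classify_skew_mechanism()` assumes lattices in the generator frame
  (or pre-aligned); `classify_mechanism()` is rigid-motion invariant but
  noise-fragile.
- The seam detector (`lattice_junctions()`) relies on
  nearest-axial-neighbour pairing and needs h well below a/2 —
  guaranteed for closure-valid specs, not for arbitrary point sets.
- The hypothesis transforms act about the lattice's own axis; applying
  them to a rigidly displaced lattice composes the displacement rather
  than failing.
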