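---
title: "pepshift: model, numerical design and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepshift: model, numerical design and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepshift)
```

## The prediction model

`pepshift` predicts backbone chemical shifts of the six nucleus classes
Cα, Cβ, C′, HN, N and Hα from a static protein structure. The model is
additive: each shift is the residue's random-coil baseline plus a weighted
sum of geometric descriptors,

$$\delta = \delta_{rc}(\text{res}, \text{nuc}) + \sum_f w_{\text{nuc},f}\, D_f.$$

The random-coil value is what the nucleus would resonate at in an
unstructured peptide; every structural effect is modelled as a deviation
from it. The descriptor families, and the exact functional forms chosen
here, are:

**Contact.** A packing term: for a query atom, the sum over all heavy
atoms at sequence separation of at least `contact_min_seq_sep` residues
(atoms on other chains always count) of the linear switching function
$1 - r/r_c$ for $r < r_c$. A linear switch was chosen over a hard count
because it is continuous in the coordinates; the radius $r_c$ (default
8 Å) and the separation threshold (default 2) are configuration.
Sequence separation is measured on residue *numbers* within a chain, so
author-assigned numbering is honoured.

**Hydrogen bond.** For each backbone amide donor N–H, the geometric value
$(1/r_{NO}) \cos(180° - \angle NHO)\cos(180° - \angle HOC')$ of the best
acceptor, where "best" means the geometrically valid acceptor
($r_{NO} \le 3.5$ Å, $\angle NHO \ge 120°$ by default) with the largest
$1/r_{NO}$, ties resolved toward the lower acceptor index. The two angle
terms are combined multiplicatively (both cosines are 1 for the ideal
collinear bond and fall off smoothly as the geometry bends). A donor never
pairs with its own residue's carbonyl or with the preceding residue's
(whose C′=O is covalently bonded to the donor nitrogen); those
"acceptors" always satisfy the distance cut for covalent rather than
hydrogen-bonding reasons. The residue-level donor value is attached to all
query nuclei of the donor residue, with per-nucleus weights deciding how
much each class feels it. Proline and the N-terminus have no amide proton
and contribute nothing.

**Magnetic anisotropy.** The axially symmetric (McConnell point-dipole)
model $\Delta\chi (1 - 3\cos^2\theta)/(3 r^3)$, evaluated for every query
proton against every backbone amide O–C′–N group and the side-chain OCN
(Asn/Gln), OCO (Asp/Glu) and NCN (Arg) groups. $r$ is the distance from
the proton to the group centroid and $\theta$ the angle between the
proton→centroid vector and the group-plane normal; $\cos^2\theta$ makes
the normal's sign irrelevant. The term vanishes at the magic angle
($\cos^2\theta = 1/3$) and decays as $r^{-3}$ — both are exact analytic
spot checks in the test suite. A proton skips any group containing an atom
of its own residue (this also removes the preceding amide group for HN,
whose nitrogen is the proton's covalent partner); bonded-neighbour effects
belong to the random-coil baseline, not the through-space term. A proton
closer than 0.5 Å to a group centroid triggers a steric-clash warning but
is still computed.

**Ring current.** The Haigh–Mallion form
$I \cdot B \cdot \sum_{(i,j)} S_{ij}(1/r_i^3 + 1/r_j^3)$ over the bonds of
each aromatic ring (Phe, Tyr, His, and both the five- and six-membered
rings of Trp). $S_{ij}$ is the signed area of the triangle spanned by the
query's in-plane projection and projected ring atoms $i, j$; the sign
convention comes from the ring frame, which fixes counter-clockwise
winding viewed from the +normal side. This reproduces the physics:
shielding above the ring plane, deshielding in the plane outside the ring.
Ring planes are least-squares (SVD) fits rather than first-three-atom
planes, for robustness to slight puckering; the in-plane basis is forced
right-handed so winding and normal stay consistent. Intensity factors $I$
per ring kind and the global scale $B$ are configuration defaults
(conventional literature-style values), not fitted ground truth.

**Dihedrals.** φ and ψ per residue, measured with the IUPAC torsion
convention (cis = 0°, trans = 180°), entering the prediction through a
truncated Fourier series $\sum_{k=1}^{3} a_k\cos k\varphi + b_k\sin
k\varphi$ (plus the same in ψ) with per-nucleus coefficients. At chain
termini, or when a backbone atom is missing, the angle is flagged absent
and contributes zero — absence is not an error. One convention note: the
IUPAC torsion of a path A–B–C–D equals that of D–C–B–A (reversal does not
negate it; mirror reflection does). The sign convention is cross-checked
in the tests against an independent torsion implementation from the bio3d
package.

## Selection, caching and the proton filter

Descriptor evaluation is preceded by a single selection pass that collects
query-nucleus indices, donors, acceptors, amide triples, side-chain groups
and rings. The selection is memoized on the structure (built exactly once,
observable via `select_eval_count()`), because rebuilding it per
descriptor call is pure waste. `clear_protons()` then removes query
protons the model cannot use: HN without a backbone N, Hα without a CA,
and any proton in a residue with an incomplete N/CA/C′ backbone. The
filter is a single linear pass and idempotent. The precise criteria are a
reconstruction — they are deliberately isolated in this one function so
they can be revised without touching anything else.

PDB reading keeps only the first MODEL (the predictor targets one static
conformer), resolves alternate locations by highest occupancy (ties: first
in file), keeps insertion codes as part of residue identity, retains
HETATM records in the atom list while excluding non-standard residues from
selection, and normalizes hydrogen-name dialects (H/HN, glycine
HA1/HA2/HA3 and 1HA/2HA) through a small synonym table. Writing goes
through `bio3d::write.pdb`.

## Two execution paths and the equivalence contract

Every descriptor family has a per-call reference implementation and a
batched one. The batched path bins coordinates into a cubic cell list
(cell edge = the family's cutoff) so each query only meets the atoms of
its 27 neighbouring cells, and both paths share the same elementwise
arithmetic kernels. Two accumulation modes exist:

* **ordered** — each query's contributions are summed in ascending
  atom/group/ring index, the same order the reference path uses. Because
  the cell list only ever *removes exact zeros* from the sum, the batched
  result equals the reference result bitwise; the engine test asserts
  agreement to ≤ 1e-12 ppm.
* **unordered** — each query's summation order is reversed (contact), or
  groups and rings are visited in descending order (anisotropy, ring
  current). This is a deterministic stand-in for the reordering a parallel
  reduction performs, and perturbs results only at the floating-point
  rounding level. The hydrogen-bond descriptor selects a maximum rather
  than accumulating a sum, so it is order-independent by construction.

The validation harness (`compare_modes()`) runs both paths over a
structure set, pools every prediction of every structure, and reports
per-nucleus RMS and maximum absolute differences,
$\mathrm{RMSE} = \sqrt{\sum_i (P_i - O_i)^2 / n}$. The acceptance
harness applies this to 20 synthetic structures and requires the pooled
statistics to stay within the envelope that a serial-vs-GPU port of this
class of predictor reports (RMS of order 1e-4 ppm, maxima of order 1e-2
ppm); the observed reference-vs-unordered differences are in fact at the
1e-16 ppm level, many orders below the envelope, because a reversed sum of
a few hundred IEEE doubles rarely moves more than one ulp.

## The synthetic generator

`build_peptide()` constructs peptides by natural-extension (NeRF) placement
with ideal covalent geometry: fixed bond lengths and angles, ω = 180°, and
φ/ψ set *exactly* to the requested values, so the geometry module must
recover them to 1e-6 degrees (a build/measure round trip, cross-checked
against bio3d's torsion code). Cβ placement picks the branch with positive
triple product about CA, i.e. L-amino acids. Aromatic rings are exact
planar polygons (hexagon angles 120°, pentagon 108°), which makes the ring
descriptor's analytic axial value reproducible to full precision;
Trp's six-membered ring is fused coplanar on the shared CD2–CE2 edge.
Side chains beyond the aromatic and anisotropy groups are reduced to their
heavy-atom skeleton with trans χ defaults, and side-chain protons are not
modelled: fixtures need exactness, not rotamer realism. Backbone HN and Hα
protons are placed when requested (no HN at the N-terminus or proline).

`build_assembly()` replicates a unit helically (copy $k$ rotated by
$k\cdot$twist about z and raised by $k\cdot$rise), giving exactly
multiplicative atom counts, unique chain labels (two-character labels with
a warning past 62), and interior copies whose descriptor environments are
identical by symmetry — the copy-symmetry oracle used in the engine tests.
`build_probe_scene()` produces three minimal geometries (axial ring probe,
collinear H-bond, axial anisotropy probe) whose descriptor values have
closed forms attached as ground truth.

`build_validation_set()` emulates the validation conditions: alternating
helix ((−57, −47)) and sheet ((−139, 135)) blocks of 6–12 residues with
6° Gaussian jitter, ≥ 10 % aromatic content (default 14 %), hydrogens
included, all under one seed. What these fixtures do *not* emulate:
packed tertiary cores, real rotamer distributions, solvent, crystal
contacts, or experimental coordinate error. Passing the dual-path
equivalence tests on them demonstrates numerical correctness of the
implementation, not predictive accuracy on real proteins — accuracy claims
would require refitting the weights against experimental shifts, which is
exactly why the shipped defaults are honest placeholders (unit weights,
zero Fourier coefficients, literature coil values).

## Fitting

`fit_parameters()` does per-nucleus ordinary least squares of the
descriptor weights against observed-minus-coil shifts, holding random-coil
values fixed by default (`fit_random_coil = TRUE` frees per-residue-type
offsets; a `ridge` option adds a closed-form ridge penalty, off by
default). Descriptor columns that are identically zero across the training
data — hydrogen bonds in hydrogen-free structures, anisotropy for
heavy-atom nuclei — are dropped from the design and keep their base
weights, which keeps the fit full-rank without pretending to information
that is not there. Under-determined designs fail loudly, naming the
nucleus. The acceptance harness checks exact recovery (≤ 1e-8) of known
generating weights from noise-free synthetic observations and recovery
within three standard errors at σ = 0.1 ppm Gaussian noise.

## Numerical choices and edge cases

* Units are Å and degrees at every interface; radians only inside
  function bodies.
* Angle computations clamp the cosine into [−1, 1] before `acos`;
  zero-length rays and collinear dihedral frames raise degenerate-geometry
  errors, while degenerate H-bond or ring geometry inside a prediction
  downgrades to a zero contribution with a warning (one bad group should
  not kill a million-atom run).
* Cutoff tests use strict/non-strict comparisons consistently (`r <
  r_c` for the contact switch, `r ≤` limits for H-bond and the
  centroid cutoffs); values beyond a cutoff are exact zeros, which is what
  makes the ordered batched path bitwise-equal to the reference.
* Ties in H-bond acceptor selection go to the lower acceptor index; the
  ascending scan makes this deterministic in both paths.
* YAML 1.1 interprets a bare `N` as a boolean, so the parameter file
  quotes the nitrogen nucleus key.

## Problem sizes

The shipped tests and acceptance harness run at desk scale by choice: the
dual-path comparison pools ~6,600 predictions from 20 structures of 56
residues; the fitting checks use 4–5 structures of 40–50 residues; the
runtime-scaling trend (Spearman correlation of batched runtime against
atom count > 0.95) uses helical assemblies of about 1.0×10³ to 1.0×10⁵
atoms. The batched path with its cell lists is the one intended for large
assemblies; the reference path exists as the semantic anchor and scales
quadratically by design.

## Known limitations

* Descriptor set limited to the five families above: no electric-field or
  solvent-exposure terms, no side-chain χ dihedrals.
* The H-bond angle-term combination (multiplicative) and the proton-filter
  criteria are reconstructions, isolated behind single functions for
  revision.
* Default parameters are not fitted to experiment; predictions with them
  are structurally meaningful but not quantitatively accurate.
* mmCIF input, protonation/repair, disulfides and ligands are out of
  scope; periodic-boundary distances are not implemented.
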