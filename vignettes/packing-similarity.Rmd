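---
title: "Packing similarity and supramolecular constructs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Packing similarity and supramolecular constructs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packmotif)
```

## The problem and the model

Molecular crystals of chemically related compounds frequently share packing
motifs even when their full structures differ: a hydrogen-bonded dimer may
survive a substituent swap while the way dimers stack changes. `packmotif`
formalizes this comparison. The unit of comparison is the **coordination
cluster**: a kernel molecule together with every symmetry/translation image
of the structure's molecules having at least one atom within the van der
Waals sum plus a margin (default 1.5&nbsp;Å) of a kernel atom. Comparing two
structures means matching the geometry of their clusters.

### Pair descriptors

Every kernel→neighbour pair is reduced to a descriptor that is invariant
under rigid motion of the whole crystal model:

* `d` — the distance between the centroids of the *correspondence points*
  (the non-hydrogen atom labels shared by the two structures' host
  molecules, ordered lexicographically);
* `u` — the unit direction of that centroid offset, expressed in the
  kernel's local frame;
* `quat` — the unit quaternion of the best proper least-squares
  superposition (Kabsch) of the neighbour's correspondence points onto the
  kernel's, in the same local frame;
* a **parity bit**: neighbours generated by an improper operator (inversion,
  glide, mirror — negative rotation determinant) are inverted through their
  centroid before superposition and flagged. Improper pairs never match
  proper ones: an inversion dimer and a translation pair can otherwise have
  deceptively similar distances and angles.

The local frame is taken from the principal axes of the centered
correspondence points, with each axis signed towards the point with the
largest projection on it and a right-handed third axis. A frame built from a
single atom triple (an earlier, simpler choice) wobbles by tens of degrees
under 0.1&nbsp;Å coordinate noise because it inherits the noise of three
atoms; the principal-axes frame averages over every correspondence point and
is stable to well under a degree at that noise level. The frame is intrinsic
to the point set, so descriptors computed in two differently oriented cells
are directly comparable. The price is a (rare) instability when two singular
values nearly coincide; for the planar-plus-pendant molecules this package
targets the spectrum is well separated.

### Matching and the dissimilarity index

Two clusters match through a greedy one-to-one assignment of shell members,
ordered by combined normalized deviation, accepting a pair only when
|Δd| ≤ `tol_d`, the angle between the `u` vectors ≤ `tol_ang`, the
quaternion angular distance ≤ `tol_ang`, and the parity bits agree. The
defaults `tol_d = 0.5` Å and `tol_ang = 12`° are wide enough to absorb the
within-motif spreads seen in real homologous families (base-vector spreads
of ~0.1 Å, conformation spreads of ~13°) and narrow enough to separate
distinct motifs in the synthetic fixtures; both are user-settable
everywhere. Greedy assignment with a deterministic tie-break (deviation,
then shell order) was chosen over optimal bipartite matching for
transparency and reproducibility; for the shell sizes involved (tens of
molecules) the two rarely differ.

The **dissimilarity index** of a match is the root-mean-square of the
tolerance-normalized deviations over all matched pairs: exactly 0 for a
self-comparison, at most 1 when every accepted pair sits on its tolerance
boundary, and increasing in expectation with coordinate noise.

### Dimensionality and base vectors

The dimensionality of a shared motif is the rank of its lattice-translation
span. Matched shell members related to the kernel by pure lattice
translation contribute their translations directly, but that alone misses an
important case: in a dimer *tape* the repeat vector (say 13.4&nbsp;Å) can
exceed the reach of a ~9&nbsp;Å molecule, so the kernel's own translate is
not in contact — the tape manifests instead as two inversion-related
neighbours one lattice step apart. The package therefore collects the
provenance *differences* of every pair of matched shell members that share
the same operator rotation in both structures (the kernel, which always
matches, counts as a member). Those differences are lattice translations of
the motif; they are reduced to a generating set by integer elimination
(components in half-integers, to accommodate lattice centerings) followed by
pairwise Lagrange size reduction against the cell metric, and the rank of
that set is the dimensionality: 0D discrete assemblies, 1D rows/stacks/
tapes, 2D layers, 3D isostructural packings. Self-comparison of a
three-dimensionally packed structure returns rank 3 with the cell vectors as
generators. Toy structures deliberately built with a non-contacting axis
have a lower-rank *contact* lattice, and their self-comparison reports that
rank — dimensionality here is a statement about the matched coordination
shells, not about the abstract lattice.

### Supramolecular constructs and the relationship graph

Family comparison runs all pairwise matches. Matched motifs are merged into
**supramolecular constructs** by descriptor congruence against the
first-seen exemplar (congruence = equal size and complete one-to-one
embedding within the matching tolerances; comparing always against one
reference avoids transitivity drift across many structures). A structure is
a member of an SC when any of its pairwise motifs *contains* the SC's
descriptor set, so a structure whose strongest relationship is 3D still
counts as exhibiting the dimer inside it. SC identifiers follow the
family-letter + dimensionality + ordinal convention (`A01`, `A11`, `B11`,
…): lineages connected by containment share a letter, ordinals follow
discovery order. Base vectors get sequential labels `t1, t2, …`, reusing a
contained SC's label when the magnitudes agree within `tol_d`.

The relationship graph places SCs at their dimensionality level and
structures on top, keeps only covering containment relations (transitive
edges removed), and supports the two canonical queries: the upward closure
of an SC (all structures containing it) and the *meet* of two structures
(their maximal common SCs).

## The synthetic-data generator

The generator emulates the study conditions the pipeline is meant for, with
a rigid toy host: a planar five-membered amide ring (N–H donor, C=O
acceptor) fused to a six-membered ring, an exocyclic methylidene carbon and
a pendant six-membered ring tilted by 42° — the midpoint of the interplanar-
angle range typical of benzylidene oxindoles (36–50°) — carrying an
exchangeable para substituent (H/F/Cl/Br) so isostructural pairs differing
in one atom can be built. Its E-configured double bond, single donor and
single acceptor are asserted by the test suite.

Motif targets are fixed at the midpoints of ranges printed for real
families: dimer N–H…O donor–acceptor distance 2.87&nbsp;Å (E-conformer range
2.844–2.904&nbsp;Å), stack translation 4.07&nbsp;Å (range 4.04–4.13), tape
translations 13.4 and 18.6&nbsp;Å. Placement directions are found by a
deterministic search over a Fibonacci sphere: a direction is feasible when
adjacent copies stay in van-der-Waals contact (≤ 3.8&nbsp;Å) without
clashing, where "clash" is element-aware — every intermolecular atom pair
must clear the covalent-radius sum by at least 0.55&nbsp;Å so that bond
perception can never fuse separate molecules, even under the coordinate
noise the generator adds (seeded isotropic Gaussian displacement of the
asymmetric unit; the seed is part of the spec and recorded in the CIF
comment, so identical specs give byte-identical files). The family fixture
additionally validates each candidate lattice by assembling the full
crystal and backtracking over ranked candidates until all seven members
build cleanly; the accepted geometry requires the 3D member's cell basis to
be Lagrange-reduced so the reported base vectors equal the construction
targets. A generation request whose placement would clash below
1.45&nbsp;Å raises an error rather than emitting an unusable structure.

Because translation chains of this bulky host along its own N–H axis always
clash, the catamer fixture uses two independent molecules per repeat — M1
donating to M2 and M2 to the next translate of M1 — with the acceptor
allowed up to ~24° off the donor axis (D–H…A stays near 144°), which is how
real catamers alternate molecular orientation.

What the toys do *not* emulate: thermal motion, realistic close-packing
density (most fixtures isolate the motif with roomy far axes), riding-model
hydrogen idealization, and disorder beyond two-conformer toggles. Passing
the recovery tests therefore demonstrates the correctness of the geometry
and matching machinery, not robustness to every artefact of experimental
refinement.

## Numerical choices and degenerate inputs

* Covalent radii follow the Cordero single-bond compilation; van der Waals
  radii follow Bondi (C 1.70, N 1.55, O 1.52, H 1.20, Cl 1.75,
  Br 1.85&nbsp;Å). Atomic weights are current conventional values; printed
  formula weights from older tables are accepted within ±0.05&nbsp;g/mol.
* Bond perception: distance ≤ covalent sum + 0.40&nbsp;Å, no H–H bonds, each
  hydrogen keeps only its nearest heavy-atom bond.
* Fractional coordinates are wrapped to [0,1) on ingest; all geometry runs
  on unwrapped Cartesian molecules (connected components of the periodic
  bond graph, breadth-first unwrapped; components that cannot be unwrapped
  consistently are flagged polymeric and excluded from cluster analysis).
* Atoms fixed by an operator (special positions) are deduplicated at
  0.3&nbsp;Å after expansion.
* Z inference scans integer candidates for a density in 0.5–3.5 g/cm³
  closest to 1.4 g/cm³; when the operator count is known, candidates are
  restricted to its multiples (plus the half-multiple for molecules on
  special positions), which is what makes the inference unambiguous for
  ordinary molecular crystals.
* Hydrogen-bond defaults (D…A ≤ 3.5&nbsp;Å, D–H…A ≥ 120°, N/O donors and
  acceptors) are generous enough to capture the 2.68–2.90&nbsp;Å /
  151–177° interactions typical of this chemistry; donors lacking modelled
  hydrogens (common for water) are reported on a separate distance-only
  candidate list.
* Mean planes come from the SVD of centered coordinates (deterministic
  normal orientation); collinear point sets raise an error. Interplanar
  angles are acute by construction.
* Hydrate waters count as molecules, are included in cluster shells by
  default (`host_only` excludes them) and are skipped by the matcher simply
  because they carry no correspondence labels.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic desk-
scale inputs: hosts of 28 atoms, cells of 1–2 molecules, families of seven
structures, twenty seeded replicates per motif-recovery claim and ~50
randomized fixtures per brute-force-oracle claim. These sizes were chosen so
every brute-force oracle (full image enumeration over ±2–3 cells) stays
exact and cheap; the pipeline itself has no intrinsic size limit beyond
O(n²) distance work per cluster.

## Known limitations

* Matching assumes a meaningful common atom-label core between structures;
  families with unrelated labelling need an explicit correspondence.
* Greedy assignment can in principle miss a larger match set that an optimal
  assignment would find near the tolerance boundary.
* The SC census compares each motif to the first-seen exemplar; radically
  heterogeneous families could split one motif into two SCs if the first
  exemplar is atypical.
* 2D layer detection has no seed-extension optimization; it relies on the
  layer's translations being present in the contact shell.
* The CIF reader covers the minimal small-molecule dialect (cell, symmetry
  operators as xyz strings, atom-site loop with fractional coordinates and
  occupancies); mmCIF/PDBx, anisotropic displacement parameters and
  reflection blocks are out of scope.
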