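Package: packmotif
Title: Crystal Packing Similarity and Supramolecular Construct Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing molecular crystal structures by the geometry of
    their packing. Reads small-molecule CIF files, expands space-group symmetry,
    perceives molecules, and reports per-structure geometry (cell metrics,
    hydrogen bonds, sub-van-der-Waals close contacts, least-squares planes and
    interplanar angles). Across a family of structures it builds
    coordination-sphere clusters around a kernel molecule, matches cluster
    geometry within tolerances, derives the dimensionality (0D-3D) and lattice
    base vectors of shared packing motifs (supramolecular constructs), and
    assembles a structure-relationship graph with strict dimensional hierarchy.
    Includes a deterministic synthetic-crystal generator for ground-truth motifs
    (inversion dimers, translation stacks, tapes, layers, isostructural pairs,
    hydrate channels, catamers).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
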