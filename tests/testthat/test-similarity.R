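# Correspondence sets, pair descriptors, cluster matching, dimensionality.

test_that("automatic correspondence takes the shared non-hydrogen core", {
  p <- build_motif_pair("isostructural_pair", noise = 0)
  stH <- p$structures[[1]]; stCl <- p$structures[[2]]
  corr <- make_correspondence(stH, stH)
  host <- packmotif:::host_molecule(stH)
  expect_setequal(as.character(corr),
                  host$atoms$label[host$atoms$element != "H"])
  # substituent-swapped pair: the common core only (no H12 / CL1)
  corr2 <- make_correspondence(stH, stCl)
  expect_false(any(c("H12", "CL1") %in% corr2))
  expect_gte(length(corr2), 16)
  # disjoint label sets
  expect_error(make_correspondence(stH, stCl, selection = c("Z1", "Z2", "Z3")),
               "missing")
})

test_that("pair descriptors capture translations and inversions", {
  st <- crystal_structure(build_crystal(motif_spec("translation_stack"))$contents)
  cl <- build_cluster(st)
  corr <- make_correspondence(st, st)
  pd <- pair_descriptor(cl, 1, corr)
  expect_equal(pd$d, 4.07, tolerance = 1e-6)
  expect_false(pd$improper)
  expect_true(pd$translation)
  expect_equal(abs(pd$quat[1]), 1, tolerance = 1e-9)  # identity rotation
  dimer <- crystal_structure(build_crystal(motif_spec("inversion_dimer"))$contents)
  cld <- build_cluster(dimer)
  pdd <- pair_descriptor(cld, 1, make_correspondence(dimer, dimer))
  expect_true(pdd$improper)
  expect_false(pdd$translation)
})

test_that("descriptors are invariant under rigid motion of the whole model", {
  host <- make_toy_molecule("host")
  m0 <- packmotif:::place_dimer_molecule(host, 2.87)
  xyz <- as.matrix(m0$atoms[, c("x", "y", "z")])
  build_from <- function(xyz_rot, L) {
    m <- m0
    m$atoms$x <- xyz_rot[, 1]; m$atoms$y <- xyz_rot[, 2]
    m$atoms$z <- xyz_rot[, 3]
    m$centroid <- colMeans(xyz_rot)
    ct <- packmotif:::contents_from_cartesian(
      "rot", list(m), L, packmotif:::spacegroup_ops("P-1"))
    crystal_structure(ct)
  }
  L0 <- diag(c(24, 26, 28))
  st0 <- build_from(xyz, L0)
  corr <- make_correspondence(st0, st0)
  d0 <- packmotif:::cluster_descriptors(build_cluster(st0), corr)
  for (seed in 1:5) {
    set.seed(seed)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    # rotating molecule and lattice together is a rigid motion of the model
    str <- build_from(xyz %*% t(R), R %*% L0)
    dr <- packmotif:::cluster_descriptors(build_cluster(str), corr)
    expect_equal(length(dr), length(d0))
    for (i in seq_along(d0)) {
      expect_equal(dr[[i]]$d, d0[[i]]$d, tolerance = 1e-6)
      expect_equal(dr[[i]]$u, d0[[i]]$u, tolerance = 1e-6)
      expect_equal(abs(sum(dr[[i]]$quat * d0[[i]]$quat)), 1, tolerance = 1e-6)
      expect_equal(dr[[i]]$improper, d0[[i]]$improper)
    }
  }
})

test_that("a cluster matched against itself matches every shell member", {
  st <- crystal_structure(build_crystal(motif_spec("isostructural_pair"))$contents)
  cl <- build_cluster(st)
  corr <- make_correspondence(st, st)
  m <- match_clusters(cl, cl, corr)
  expect_equal(nrow(m), length(cl$shell))
  expect_equal(dissimilarity_index(m), 0, tolerance = 1e-9)
})

test_that("noisy isostructural copies match fully; tolerances are monotone", {
  p <- build_motif_pair("isostructural_pair", seed = 3, noise = 0.05)
  corr <- make_correspondence(p$structures[[1]], p$structures[[2]])
  cl1 <- build_cluster(p$structures[[1]])
  cl2 <- build_cluster(p$structures[[2]])
  m <- match_clusters(cl1, cl2, corr)
  expect_equal(nrow(m), min(length(cl1$shell), length(cl2$shell)))
  # enlarging tolerances never reduces the matched count
  sizes <- vapply(list(c(0.1, 3), c(0.3, 8), c(0.5, 12), c(1.0, 20)),
                  function(tl) {
                    nrow(match_clusters(cl1, cl2, corr, tol_d = tl[1],
                                        tol_ang = tl[2]))
                  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("comparison is symmetric in its arguments", {
  for (kind in c("translation_stack", "isostructural_pair")) {
    p <- build_motif_pair(kind, seed = 6, noise = 0.03)
    ab <- compare_structures(p$structures[[1]], p$structures[[2]])
    ba <- compare_structures(p$structures[[2]], p$structures[[1]])
    expect_equal(ab$motif$dimensionality, ba$motif$dimensionality)
    expect_equal(sort(ab$motif$magnitudes), sort(ba$motif$magnitudes),
                 tolerance = 1e-6)
  }
})

test_that("dimensionality and base vectors recover the construction", {
  # 0D: inversion dimer partner only
  p0 <- build_motif_pair("inversion_dimer", seed = 2, noise = 0.02)
  m0 <- compare_structures(p0$structures[[1]], p0$structures[[2]])$motif
  expect_equal(m0$dimensionality, 0)
  expect_equal(length(m0$magnitudes), 0)
  # 1D stack at 4.07
  p1 <- build_motif_pair("translation_stack", seed = 2, noise = 0.02)
  m1 <- compare_structures(p1$structures[[1]], p1$structures[[2]])$motif
  expect_equal(m1$dimensionality, 1)
  expect_equal(m1$magnitudes, 4.07, tolerance = 1e-6)
  # self comparison: 3D with the cell vectors
  st <- p1$structures[[1]]
  iso <- crystal_structure(build_crystal(motif_spec("isostructural_pair"))$contents)
  ms <- compare_structures(iso, iso)$motif
  expect_equal(ms$dimensionality, 3)
  expect_equal(sort(ms$magnitudes),
               sort(c(iso$cell$a, iso$cell$b, iso$cell$c)), tolerance = 1e-9)
})

test_that("the dissimilarity index is normalized and increases with noise", {
  p <- build_motif_pair("translation_stack", seed = 11, noise = 0.04)
  m <- compare_structures(p$structures[[1]], p$structures[[2]])$match
  di <- dissimilarity_index(m)
  expect_gt(di, 0)
  expect_lte(di, 1)
  expect_error(dissimilarity_index(m[0, ]), "undefined")
  # paired replicates: low noise scores below high noise almost always
  wins <- 0L
  n_rep <- 25L
  for (seed in seq_len(n_rep)) {
    pa <- build_motif_pair("inversion_dimer", seed = 1000 + seed, noise = 0.02)
    pb <- build_motif_pair("inversion_dimer", seed = 1000 + seed, noise = 0.10)
    da <- dissimilarity_index(
      compare_structures(pa$structures[[1]], pa$structures[[2]])$match)
    db <- dissimilarity_index(
      compare_structures(pb$structures[[1]], pb$structures[[2]])$match)
    if (da < db) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.9 * n_rep))
})
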