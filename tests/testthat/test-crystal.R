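# Symmetry expansion, bond perception, molecule assembly, disorder, E/Z.

test_that("orthogonalization maps fractional axes onto the cell geometry", {
  cell <- unit_cell(10, 20, 30)
  expect_equal(frac_to_cart(cell, c(0.5, 0.5, 0.5)), c(5, 10, 15))
  set.seed(7)
  for (i in 1:10) {
    cl <- unit_cell(runif(1, 5, 15), runif(1, 5, 15), runif(1, 5, 15),
                    runif(1, 75, 105), runif(1, 75, 105), runif(1, 75, 105))
    b_img <- frac_to_cart(cl, c(0, 1, 0))
    a_img <- frac_to_cart(cl, c(1, 0, 0))
    expect_equal(sqrt(sum(b_img^2)), cl$b, tolerance = 1e-9)
    gamma <- acos(sum(a_img * b_img) / (cl$a * cl$b)) * 180 / pi
    expect_equal(gamma, cl$gamma, tolerance = 1e-9)
    # round trip
    p <- runif(3)
    expect_equal(cart_to_frac(cl, frac_to_cart(cl, p)), p, tolerance = 1e-10)
  }
  # parallelepiped volume of the basis images equals the cell volume (3c)
  c3c <- unit_cell(4.1302, 12.9513, 13.0829, 62.708, 86.495, 86.546)
  expect_equal(abs(det(cell_orthomatrix(c3c))), 620.35, tolerance = 0.1 / 620)
})

test_that("bond perception matches an all-pairs oracle and the H rules", {
  two <- function(d) tibble::tibble(label = c("C1", "C2"),
                                    element = "C", x = c(0, d), y = 0, z = 0)
  expect_equal(nrow(perceive_bonds(two(1.50))), 1L)
  expect_equal(nrow(perceive_bonds(two(3.00))), 0L)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    at <- tibble::tibble(label = paste0("A", 1:n),
                         element = sample(c("C", "N", "O", "H"), n, TRUE),
                         x = runif(n, 0, 6), y = runif(n, 0, 6),
                         z = runif(n, 0, 6))
    got <- perceive_bonds(at)
    # oracle: plain double loop with the same covalent criterion, then the
    # hydrogen constraints applied independently
    keys <- character(0)
    h_best <- list()
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (at$element[i] == "H" && at$element[j] == "H") next
        d <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) -
                         c(at$x[j], at$y[j], at$z[j]))^2))
        if (d <= covalent_radius(at$element[i]) +
            covalent_radius(at$element[j]) + 0.40) {
          keys <- c(keys, paste(i, j))
        }
      }
    }
    # hydrogen keeps only its nearest bond
    for (h in which(at$element == "H")) {
      inv <- keys[vapply(strsplit(keys, " "),
                         function(p) any(as.integer(p) == h), logical(1))]
      if (length(inv) > 1) {
        dists <- vapply(strsplit(inv, " "), function(p) {
          p <- as.integer(p)
          o <- setdiff(p, h)
          sqrt(sum((c(at$x[h], at$y[h], at$z[h]) -
                      c(at$x[o], at$y[o], at$z[o]))^2))
        }, numeric(1))
        keys <- setdiff(keys, inv[-which.min(dists)])
      }
    }
    expect_setequal(paste(got[, 1], got[, 2]), keys)
  }
})

test_that("symmetry expansion yields operator-count x site-count distinct positions", {
  st <- crystal_structure(build_crystal(motif_spec("inversion_dimer"))$contents)
  ex <- packmotif:::expand_sites(st$contents)
  expect_equal(nrow(ex), 2L * nrow(st$contents$sites))
  cart <- frac_to_cart(st$cell, as.matrix(ex[, c("fx", "fy", "fz")]))
  expect_gt(min(dist(cart)), 0.3)
})

test_that("molecule assembly finds the ground-truth census", {
  # toy P1 hydrate: host + water -> 2 molecules
  hyd <- build_crystal(motif_spec("hydrate_channel"))
  st <- crystal_structure(hyd$contents)
  expect_equal(length(st$molecules), 2L)
  # P-1 structure: 1 representative, 2 images per cell
  dim_st <- crystal_structure(build_crystal(motif_spec("inversion_dimer"))$contents)
  expect_equal(length(dim_st$molecules), 1L)
  expect_equal(dim_st$n_images, 2L)
  # unwrapped molecules are contiguous: no bond longer than the cutoff
  mol <- dim_st$molecules[[1]]
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
    d <- sqrt(sum((c(mol$atoms$x[i], mol$atoms$y[i], mol$atoms$z[i]) -
                     c(mol$atoms$x[j], mol$atoms$y[j], mol$atoms$z[j]))^2))
    expect_lt(d, covalent_radius(mol$atoms$element[i]) +
                covalent_radius(mol$atoms$element[j]) + 0.40)
  }
})

test_that("assembly is invariant to site order", {
  syn <- build_crystal(motif_spec("hydrate_channel", seed = 4))
  ct <- syn$contents
  set.seed(1)
  ct2 <- ct
  perm <- sample(nrow(ct$sites))
  ct2$sites <- ct$sites[perm, ]
  s1 <- crystal_structure(ct)
  s2 <- crystal_structure(ct2)
  k1 <- sort(vapply(s1$molecules, packmotif:::molecule_label_key, character(1)))
  k2 <- sort(vapply(s2$molecules, packmotif:::molecule_label_key, character(1)))
  expect_identical(k1, k2)
})

test_that("atoms on special positions are deduplicated (C2/c twofold)", {
  # oxygen on the C2/c twofold axis (0, y, 1/4): multiplicity 4, not 8
  cell <- unit_cell(19.6, 4.07, 32.9, 90, 101.7, 90)
  sites <- tibble::tibble(label = "O1W", element = "O",
                          x = 0, y = 0.35, z = 0.25, occupancy = 1)
  ct <- cell_contents("c2c_special", cell, packmotif:::spacegroup_ops("C2/c"),
                      sites)
  ex <- packmotif:::expand_sites(ct)
  expect_equal(nrow(ex), 4L)
})

test_that("major conformers are selected from disorder groups", {
  cell <- unit_cell(10, 10, 10)
  sites <- tibble::tibble(
    label = c("C1", "C2A", "C2B"), element = "C",
    x = c(0.1, 0.30, 0.33), y = 0.2, z = 0.2,
    occupancy = c(1, 0.7, 0.3))
  out <- select_major_conformer(sites, cell)
  expect_equal(out$label, c("C1", "C2A"))
  # all-ordered input unchanged
  sites2 <- sites
  sites2$occupancy <- 1
  expect_identical(select_major_conformer(sites2, cell), sites2)
  # downstream: a two-conformer ring still assembles to one molecule
  host <- make_toy_molecule("host")
  xyz <- as.matrix(host$atoms[, c("x", "y", "z")])
  alt <- host$atoms[host$atoms$label %in% c("C10", "C11"), ]
  alt$label <- paste0(alt$label, "B")
  alt$x <- alt$x + 0.3
  alt$occupancy <- 0.4
  at <- dplyr::bind_rows(host$atoms, alt)
  at$occupancy[at$label %in% c("C10", "C11")] <- 0.6
  f <- cart_to_frac(unit_cell(25, 26, 27), as.matrix(at[, c("x", "y", "z")]) + 8)
  ct <- cell_contents("disorder", unit_cell(25, 26, 27),
                      list(parse_symop("x, y, z")),
                      tibble::tibble(label = at$label, element = at$element,
                                     x = f[, 1], y = f[, 2], z = f[, 3],
                                     occupancy = at$occupancy))
  st <- crystal_structure(ct)
  expect_equal(length(st$molecules), 1L)
  expect_equal(nrow(st$molecules[[1]]$atoms), nrow(host$atoms))
})

test_that("exocyclic C=C geometry classifies as E or Z by torsion", {
  # planar fragment ref1-C=C-ref2 built at a given torsion
  frag <- function(torsion_deg) {
    t <- torsion_deg * pi / 180
    atoms <- tibble::tibble(
      label = c("R1", "A1", "A2", "R2"), element = "C",
      x = c(-0.6, 0, 1.34, 1.94),
      y = c(1.04, 0, 0, 1.04 * cos(t)),
      z = c(0, 0, 0, 1.04 * sin(t)))
    mol <- list(atoms = atoms, bonds = matrix(c(1L, 2L, 2L, 3L, 3L, 4L),
                                              ncol = 2, byrow = TRUE),
                centroid = colMeans(as.matrix(atoms[, c("x", "y", "z")])))
    class(mol) <- "molecule"
    mol
  }
  expect_equal(as.character(classify_cc_geometry(frag(180), c("A1", "A2"),
                                                 c("R1", "R2"))), "E")
  expect_equal(as.character(classify_cc_geometry(frag(0), c("A1", "A2"),
                                                 c("R1", "R2"))), "Z")
  # the toy host is built as the E isomer
  host <- make_toy_molecule("host")
  expect_equal(as.character(classify_cc_geometry(host, c("C3", "C8"),
                                                 c("C2", "C9"))), "E")
  expect_error(classify_cc_geometry(host, c("C3", "C8"), c("C2", "ZZ9")),
               "missing")
})
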