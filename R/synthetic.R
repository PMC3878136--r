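# Synthetic ground-truth crystals: a rigid planar host with an N-H donor, a
# C=O acceptor and a tilted pendant ring, assembled into the packing motifs
# the pipeline must recover (inversion dimer, translation stacks and tapes,
# layers, isostructural pairs, hydrate channels, catamers), with seeded
# coordinate noise and a ground-truth record alongside every structure.

rot_xy <- function(p, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2], p[3])
}

rotate_about <- function(points, origin, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  sweep(t(apply(sweep(points, 2, origin), 1, function(v) {
    v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
  })), 2, -origin)
}

run_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.synthetic_cache <- new.env(parent = emptyenv())

.substituent_geom <- list(H = list(label = "H12", element = "H", len = 1.08),
                          F = list(label = "F1", element = "F", len = 1.35),
                          Cl = list(label = "CL1", element = "Cl", len = 1.73),
                          Br = list(label = "BR1", element = "Br", len = 1.90))

#' Build the toy host or water molecule template
#'
#' The host mimics a methylidene-oxindole-like scaffold: a planar bicyclic
#' core (five-membered ring with amide N-H donor and carbonyl C=O acceptor,
#' fused benzo ring) bearing an exocyclic methylidene carbon and a pendant
#' six-membered ring tilted by a fixed 42 degrees relative to the core plane
#' (the midpoint of the interplanar-angle range typical of this compound
#' family). The pendant ring carries a variable para substituent so
#' isostructural pairs differing only in that atom can be generated.
#'
#' @param kind `"host"` or `"water"`.
#' @param substituent Para substituent of the host pendant ring: one of
#'   `"H"`, `"F"`, `"Cl"`, `"Br"`.
#' @param tilt Pendant-ring tilt angle in degrees (default 42).
#' @return A molecule object (atoms tibble, perceived bonds, centroid).
#' @export
make_toy_molecule <- function(kind = c("host", "water"), substituent = "H",
                              tilt = 42) {
  kind <- match.arg(kind)
  if (kind == "water") {
    a <- 104.5 / 2 * pi / 180
    atoms <- tibble::tibble(
      label = c("O1W", "H1W", "H2W"), element = c("O", "H", "H"),
      x = c(0, 0.96 * sin(a), -0.96 * sin(a)),
      y = c(0, 0.96 * cos(a), 0.96 * cos(a)),
      z = 0, occupancy = 1)
    mol <- list(atoms = atoms, bonds = perceive_bonds(atoms),
                provenance = list(op = 1L, shift = c(0L, 0L, 0L)),
                centroid = colMeans(as.matrix(atoms[, c("x", "y", "z")])))
    class(mol) <- "molecule"
    return(mol)
  }
  sub <- .substituent_geom[[substituent]]
  if (is.null(sub)) {
    stop("unsupported substituent '", substituent, "'", call. = FALSE)
  }
  r5 <- 1.40 / (2 * sin(pi / 5))
  pent <- function(deg) c(r5 * cos(deg * pi / 180), r5 * sin(deg * pi / 180), 0)
  N1 <- pent(90); C2 <- pent(18); C3 <- pent(-54)
  C3A <- pent(-126); C7A <- pent(162)
  unitv <- function(v) v / sqrt(sum(v^2))
  O1 <- C2 + 1.22 * unitv(C2)
  H1 <- N1 + 1.01 * unitv(N1)
  # fused benzo ring sharing the C3A-C7A edge
  m <- (C3A + C7A) / 2
  hc <- m + unitv(m) * 1.40 * sqrt(3) / 2
  step <- if (sqrt(sum((rot_xy(C3A - hc, 60) + hc - C7A)^2)) < 0.1) -60 else 60
  benzo <- lapply(1:4, function(k) rot_xy(C3A - hc, step * k) + hc)
  names(benzo) <- c("C4", "C5", "C6", "C7")
  benzo_h <- lapply(benzo, function(p) p + 1.08 * unitv(p - hc))
  # exocyclic methylidene and pendant ring
  dir8 <- unitv(C3)
  C8 <- C3 + 1.35 * dir8
  side <- function(p) sign((C8[1] - C3[1]) * (p[2] - C3[2]) -
                             (C8[2] - C3[2]) * (p[1] - C3[1]))
  d9a <- rot_xy(dir8, 55); d9b <- rot_xy(dir8, -55)
  d9 <- if (side(C8 + d9a) != side(C2)) d9a else d9b  # anti to carbonyl side (E)
  C9 <- C8 + 1.47 * d9
  H8 <- C8 + 1.08 * unitv(rot_xy(dir8, if (all(d9 == d9a)) -120 else 120))
  rc <- C9 + 1.39 * unitv(C9 - C8)
  ring <- lapply(0:5, function(k) rot_xy(C9 - rc, 60 * k) + rc)
  names(ring) <- c("C9", "C10", "C11", "C12", "C13", "C14")
  ring_h <- lapply(ring[c("C10", "C11", "C13", "C14")],
                   function(p) p + 1.08 * unitv(p - rc))
  sub_pos <- ring$C12 + sub$len * unitv(ring$C12 - rc)
  pend_lbl <- c("C10", "C11", "C12", "C13", "C14",
                "H10", "H11", "H13", "H14", sub$label)
  pend <- rbind(do.call(rbind, ring[c("C10", "C11", "C12", "C13", "C14")]),
                do.call(rbind, ring_h), sub_pos)
  pend <- rotate_about(pend, C9, unitv(C9 - C8), tilt)
  atoms <- tibble::tibble(
    label = c("N1", "H1", "C2", "O1", "C3", "C3A", "C7A",
              names(benzo), paste0("H", 4:7), "C8", "H8", "C9", pend_lbl),
    element = c("N", "H", "C", "O", "C", "C", "C", rep("C", 4), rep("H", 4),
                "C", "H", "C", rep("C", 5), rep("H", 4), sub$element),
    occupancy = 1)
  xyz <- rbind(N1, H1, C2, O1, C3, C3A, C7A, do.call(rbind, benzo),
               do.call(rbind, benzo_h), C8, H8, C9, pend)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  mol <- list(atoms = atoms, bonds = perceive_bonds(atoms),
              provenance = list(op = 1L, shift = c(0L, 0L, 0L)),
              centroid = colMeans(xyz))
  class(mol) <- "molecule"
  mol
}

# Deterministic Fibonacci sphere of unit directions.
sphere_directions <- function(n = 500) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

min_pair_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

# Minimum of (distance - covalent-radius sum) over all atom pairs: placements
# must keep this above the bond-perception cutoff (0.40 + noise margin) so
# separate molecules never fuse.
min_cov_clearance <- function(a, el_a, b, el_b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  min(sqrt(d2) - outer(covalent_radius(el_a), covalent_radius(el_b), "+"))
}

# Combined feasibility for a candidate translation of a repeat unit.
placement_ok <- function(unit_xyz, elements, shifted_xyz, lo = 1.7,
                         cov_margin = 0.55) {
  min_pair_distance(unit_xyz, shifted_xyz) >= lo &&
    min_cov_clearance(unit_xyz, elements, shifted_xyz, elements) >= cov_margin
}

# Feasible translation directions for repeating `unit_xyz` at `magnitude`:
# adjacent copies must neither clash/fuse (element-aware clearance via
# placement_ok) nor lose contact, where contact is measured between copies of
# `contact_xyz` (defaults to the whole unit). Ranked by closeness of the
# contact to `prefer`.
find_directions <- function(unit_xyz, magnitude, elements,
                            contact_xyz = unit_xyz, lo = 1.7, hi = 3.8,
                            prefer = 2.8, n = 500) {
  dirs <- sphere_directions(n)
  score <- rep(NA_real_, nrow(dirs))
  mind <- rep(NA_real_, nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    T1 <- magnitude * dirs[k, ]
    dc <- min_pair_distance(contact_xyz, sweep(contact_xyz, 2, T1, "+"))
    if (dc > hi) next
    ok <- placement_ok(unit_xyz, elements,
                       sweep(unit_xyz, 2, T1, "+"), lo = lo) &&
      placement_ok(unit_xyz, elements, sweep(unit_xyz, 2, 2 * T1, "+"),
                   lo = lo)
    if (ok) {
      score[k] <- abs(dc - prefer)
      mind[k] <- dc
    }
  }
  ok <- which(!is.na(score))
  if (length(ok) == 0) {
    stop("no feasible translation direction at magnitude ", magnitude,
         call. = FALSE)
  }
  list(dirs = dirs[ok[order(score[ok])], , drop = FALSE],
       min_dist = mind[ok[order(score[ok])]])
}

# Pick up to `k` feasible directions pairwise separated by >= sep_deg
# (also counting antiparallel duplicates).
pick_separated_directions <- function(cands, k, sep_deg = 25) {
  chosen <- list()
  for (r in seq_len(nrow(cands))) {
    v <- cands[r, ]
    ok <- all(vapply(chosen, function(w) {
      ang <- acos(min(1, abs(sum(v * w)))) * 180 / pi
      ang >= sep_deg
    }, logical(1)))
    if (ok) chosen[[length(chosen) + 1L]] <- v
    if (length(chosen) == k) break
  }
  if (length(chosen) < k) {
    stop("could not find ", k, " separated translation directions",
         call. = FALSE)
  }
  do.call(rbind, chosen)
}

# Orthonormal vectors completing `v` (unit) to a right-handed frame.
complete_frame <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * v) * v
  e2 <- e2 / sqrt(sum(e2^2))
  rbind(e2, pracma_cross(v, e2))
}

# Assemble cell contents from Cartesian molecules + cell vector matrix
# (columns are the cell vectors). Noise is seeded isotropic Gaussian
# displacement applied to the stored (asymmetric-unit) coordinates.
contents_from_cartesian <- function(id, mols, lattice, ops, noise = 0,
                                    seed = 1) {
  L <- lattice
  # cell parameters + fractional coordinates only preserve geometry up to
  # the handedness of the basis: force a right-handed one
  if (det(L) < 0) L[, 3] <- -L[, 3]
  lens <- sqrt(colSums(L^2))
  ang <- function(i, j) acos(sum(L[, i] * L[, j]) / (lens[i] * lens[j])) * 180 / pi
  cell <- unit_cell(lens[1], lens[2], lens[3], ang(2, 3), ang(1, 3), ang(1, 2))
  xyz <- do.call(rbind, lapply(mols, function(m) {
    as.matrix(m$atoms[, c("x", "y", "z")])
  }))
  if (noise > 0) {
    xyz <- xyz + run_with_seed(seed, matrix(stats::rnorm(length(xyz), 0, noise),
                                            nrow(xyz), 3))
  }
  f <- t(solve(L) %*% t(xyz))
  sites <- tibble::tibble(
    label = unlist(lapply(mols, function(m) m$atoms$label)),
    element = unlist(lapply(mols, function(m) m$atoms$element)),
    x = f[, 1], y = f[, 2], z = f[, 3],
    occupancy = unlist(lapply(mols, function(m) m$atoms$occupancy)))
  cell_contents(id, cell, ops, sites)
}

# Smallest intermolecular atom-atom distance over all symmetry images.
min_intermolecular_distance <- function(structure) {
  best <- Inf
  for (mol in structure$molecules) {
    reach <- 2 * mol_radius(mol) + 6
    for (rec in enumerate_images(structure, mol$centroid, reach)) {
      if (same_image(rec, mol)) next
      d <- min_pair_distance(as.matrix(mol$atoms[, c("x", "y", "z")]),
                             as.matrix(rec$molecule$atoms[, c("x", "y", "z")]))
      best <- min(best, d)
    }
  }
  best
}

#' Specify a synthetic crystal motif
#'
#' @param kind One of `"inversion_dimer"`, `"translation_stack"`,
#'   `"sheared_tape"`, `"layer"`, `"isostructural_pair"`,
#'   `"hydrate_channel"`, `"catamer"`.
#' @param base Target base-vector magnitude(s) in Angstrom (defaults per
#'   kind: stack 4.07, sheared tape 13.4, dimer none).
#' @param noise Isotropic Gaussian coordinate displacement sigma in Angstrom.
#' @param seed Integer seed; together with the spec it fully determines the
#'   output.
#' @param substituent Host para substituent (`"H"`, `"F"`, `"Cl"`, `"Br"`).
#' @param d_da Target donor...acceptor distance of the dimer/chain hydrogen
#'   bond in Angstrom (default 2.87, the midpoint of typical printed ranges).
#' @return List of class `motif_spec`.
#' @export
motif_spec <- function(kind, base = NULL, noise = 0, seed = 1,
                       substituent = "H", d_da = 2.87) {
  kinds <- c("inversion_dimer", "translation_stack", "sheared_tape", "layer",
             "isostructural_pair", "hydrate_channel", "catamer")
  if (!kind %in% kinds) {
    stop("unknown motif kind '", kind, "'", call. = FALSE)
  }
  base <- base %||% switch(kind,
    translation_stack = 4.07, sheared_tape = 13.4, hydrate_channel = 4.07,
    NULL)
  structure(list(kind = kind, base = base, noise = noise, seed = seed,
                 substituent = substituent, d_da = d_da),
            class = "motif_spec")
}

# Host molecule translated so that the inversion image across the origin
# accepts its N-H at the target D...A distance.
place_dimer_molecule <- function(host, d_da) {
  at <- host$atoms
  N1 <- as.numeric(at[at$label == "N1", c("x", "y", "z")])
  H1 <- as.numeric(at[at$label == "H1", c("x", "y", "z")])
  O1 <- as.numeric(at[at$label == "O1", c("x", "y", "z")])
  u <- (H1 - N1) / sqrt(sum((H1 - N1)^2))
  t <- -(N1 + O1 + d_da * u) / 2
  m <- host
  m$atoms$x <- m$atoms$x + t[1]
  m$atoms$y <- m$atoms$y + t[2]
  m$atoms$z <- m$atoms$z + t[3]
  m$centroid <- host$centroid + t
  m
}

mol_xyz <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

bbox_extent <- function(xyz) apply(xyz, 2, function(v) diff(range(v)))

# Rotate a molecule into its principal-axes frame (deterministic signs).
principal_frame <- function(mol) {
  xyz <- sweep(mol_xyz(mol), 2, mol$centroid)
  ev <- eigen(crossprod(xyz), symmetric = TRUE)
  V <- ev$vectors[, order(-ev$values)]
  for (j in 1:3) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  if (det(V) < 0) V[, 3] <- -V[, 3]
  out <- mol
  r <- xyz %*% V
  out$atoms$x <- r[, 1]; out$atoms$y <- r[, 2]; out$atoms$z <- r[, 3]
  out$centroid <- c(0, 0, 0)
  out
}

#' Build a synthetic ground-truth crystal
#'
#' Constructs the requested packing motif and returns the CIF-serializable
#' cell contents together with a ground-truth record (expected molecules per
#' cell, expected hydrogen bonds, expected shared-motif dimensionality and
#' base-vector magnitudes). Identical spec + seed give byte-identical CIF
#' output; a clash between non-bonded atoms closer than 1.45 Angstrom after
#' placement raises a generation error.
#'
#' @param spec A [motif_spec()].
#' @param structure_id Identifier for the generated structure.
#' @return List of class `synthetic_crystal` with elements `contents`
#'   ([cell_contents()]) and `truth`.
#' @export
build_crystal <- function(spec, structure_id = NULL) {
  stopifnot(inherits(spec, "motif_spec"))
  host <- make_toy_molecule("host", substituent = spec$substituent)
  id <- structure_id %||% paste0("toy_", spec$kind, "_s", spec$seed)
  truth <- list(kind = spec$kind, seed = spec$seed, noise = spec$noise,
                interplanar = 42)

  if (spec$kind == "inversion_dimer") {
    m0 <- place_dimer_molecule(host, spec$d_da)
    ext <- bbox_extent(rbind(mol_xyz(m0), -mol_xyz(m0)))
    L <- diag(ext + 9)
    contents <- contents_from_cartesian(id, list(m0), L, spacegroup_ops("P-1"),
                                        spec$noise, spec$seed)
    truth <- c(truth, list(molecules_per_cell = 2, dimensionality = 0,
                           base_magnitudes = numeric(0),
                           hbonds = tibble::tibble(donor = "N1",
                                                   acceptor = "O1",
                                                   d_da = spec$d_da)))
  } else if (spec$kind %in% c("translation_stack", "hydrate_channel")) {
    t_mag <- spec$base[1]
    dirs <- find_directions(mol_xyz(host), t_mag, host$atoms$element)
    A <- t_mag * dirs$dirs[1, ]
    Fr <- complete_frame(A)
    ext <- bbox_extent(mol_xyz(host))
    L <- cbind(A, (max(ext) + 9) * Fr[1, ], (max(ext) + 11) * Fr[2, ])
    mols <- list(host)
    hb <- tibble::tibble(donor = character(0), acceptor = character(0),
                         d_da = numeric(0))
    n_mol <- 1
    if (spec$kind == "hydrate_channel") {
      # water donating to the host carbonyl, displaced off the core plane
      at <- host$atoms
      O1 <- as.numeric(at[at$label == "O1", c("x", "y", "z")])
      C2 <- as.numeric(at[at$label == "C2", c("x", "y", "z")])
      w_dir <- (O1 - C2) / sqrt(sum((O1 - C2)^2))
      w_dir <- w_dir + c(0, 0, 0.45)
      w_dir <- w_dir / sqrt(sum(w_dir^2))
      Ow <- O1 + 2.80 * w_dir
      wat <- make_toy_molecule("water")
      # orient: H1W along Ow -> O1
      h1 <- Ow + 0.96 * (O1 - Ow) / 2.80
      perp <- complete_frame((O1 - Ow) / 2.80)[1, ]
      a2 <- (104.5 - 0) * pi / 180
      h2 <- Ow + 0.96 * (cos(a2) * (O1 - Ow) / 2.80 + sin(a2) * perp)
      wat$atoms$x <- c(Ow[1], h1[1], h2[1])
      wat$atoms$y <- c(Ow[2], h1[2], h2[2])
      wat$atoms$z <- c(Ow[3], h1[3], h2[3])
      wat$centroid <- colMeans(mol_xyz(wat))
      mols <- list(host, wat)
      hb <- dplyr::bind_rows(hb, tibble::tibble(donor = "O1W",
                                                acceptor = "O1", d_da = 2.80))
      n_mol <- 2
    }
    contents <- contents_from_cartesian(id, mols, L, spacegroup_ops("P1"),
                                        spec$noise, spec$seed)
    truth <- c(truth, list(molecules_per_cell = n_mol, dimensionality = 1,
                           base_magnitudes = t_mag,
                           hbonds = if (spec$kind == "hydrate_channel") hb else
                             hb[0, ]))
  } else if (spec$kind == "sheared_tape") {
    m0 <- place_dimer_molecule(host, spec$d_da)
    dimer <- rbind(mol_xyz(m0), -mol_xyz(m0))
    t_mag <- spec$base[1]
    dirs <- find_directions(dimer, t_mag, rep(host$atoms$element, 2))
    A <- t_mag * dirs$dirs[1, ]
    Fr <- complete_frame(A)
    ext <- max(bbox_extent(dimer))
    L <- cbind(A, (ext + 9) * Fr[1, ], (ext + 11) * Fr[2, ])
    contents <- contents_from_cartesian(id, list(m0), L, spacegroup_ops("P-1"),
                                        spec$noise, spec$seed)
    truth <- c(truth, list(molecules_per_cell = 2, dimensionality = 1,
                           base_magnitudes = t_mag,
                           hbonds = tibble::tibble(donor = "N1",
                                                   acceptor = "O1",
                                                   d_da = spec$d_da)))
  } else if (spec$kind %in% c("layer", "isostructural_pair")) {
    # size the box on the largest substituent so swapped variants share a cell
    big <- principal_frame(make_toy_molecule("host", substituent = "Cl"))
    ext <- bbox_extent(mol_xyz(big))
    mol <- principal_frame(host)
    gaps <- if (spec$kind == "layer") c(2.9, 2.9, 9.5) else c(2.9, 2.9, 2.9)
    L <- diag(ext + gaps)
    contents <- contents_from_cartesian(id, list(mol), L, spacegroup_ops("P1"),
                                        spec$noise, spec$seed)
    dim_true <- if (spec$kind == "layer") 2 else 3
    mags <- sort(diag(L))[seq_len(dim_true)]
    if (spec$kind == "layer") mags <- sort(diag(L)[1:2])
    truth <- c(truth, list(molecules_per_cell = 1, dimensionality = dim_true,
                           base_magnitudes = mags,
                           hbonds = tibble::tibble(donor = character(0),
                                                   acceptor = character(0),
                                                   d_da = numeric(0))))
  } else if (spec$kind == "catamer") {
    # chain without dimer closure: two independent molecules per repeat,
    # M1 donating to M2 and M2 donating to the next translate of M1, so
    # successive molecules alternate orientation as in real catamers
    at <- host$atoms
    pick <- function(l) as.numeric(at[at$label == l, c("x", "y", "z")])
    N1 <- pick("N1"); H1 <- pick("H1"); O1 <- pick("O1")
    u1 <- (H1 - N1) / sqrt(sum((H1 - N1)^2))
    X1 <- mol_xyz(host)
    rotmat <- function(axis, deg) {
      k <- axis / sqrt(sum(axis^2)); a <- deg * pi / 180
      K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
    }
    # deterministic orientation scan: the acceptor may sit up to ~24 degrees
    # off the N-H axis (D-H...A stays >= ~140 degrees) and the second
    # molecule's orientation is free; cached per (substituent, d_da)
    cache_key <- paste0("catamer_", spec$substituent, "_", spec$d_da)
    best <- .synthetic_cache[[cache_key]]
    if (is.null(best)) {
      perp <- c(1, 0, 0)
      for (delta in c(0, 12, 24)) {
        for (psi in seq(0, 315, by = 45)) {
          ax <- as.numeric(rotmat(u1, psi) %*% perp)
          ax <- ax - sum(ax * u1) * u1
          ax <- ax / sqrt(sum(ax^2))
          w1 <- as.numeric(rotmat(ax, delta) %*% u1)
          for (alpha in seq(30, 330, by = 15)) {
            for (gamma in seq(0, 345, by = 15)) {
              R2 <- rotmat(c(0, 0, 1), gamma) %*% rotmat(c(1, 0, 0), alpha)
              s <- N1 + spec$d_da * w1 - as.numeric(R2 %*% O1)
              X2 <- t(R2 %*% t(X1)) + matrix(s, nrow(X1), 3, byrow = TRUE)
              N1b <- as.numeric(R2 %*% N1) + s
              w2 <- as.numeric(R2 %*% w1)
              T1 <- N1b + spec$d_da * w2 - O1
              if (sqrt(sum(T1^2)) < 5) next
              U <- rbind(X1, X2)
              elU <- rep(at$element, 2)
              feas <- placement_ok(X1, at$element, X2) &&
                placement_ok(U, elU, sweep(U, 2, T1, "+")) &&
                placement_ok(U, elU, sweep(U, 2, 2 * T1, "+"))
              if (!feas) next
              clr <- min(min_cov_clearance(X1, at$element, X2, at$element),
                         min_cov_clearance(U, elU, sweep(U, 2, T1, "+"), elU))
              if (is.null(best) || clr > best$dmin) {
                best <- list(R2 = R2, s = s, T1 = T1, dmin = clr)
              }
            }
          }
        }
      }
      .synthetic_cache[[cache_key]] <- best
    }
    if (is.null(best)) {
      stop("unrealizable spec: no clash-free catamer chain geometry",
           call. = FALSE)
    }
    m2 <- host
    X2 <- t(best$R2 %*% t(X1)) + matrix(best$s, nrow(X1), 3, byrow = TRUE)
    m2$atoms$label <- paste0(m2$atoms$label, "B")
    m2$atoms$x <- X2[, 1]; m2$atoms$y <- X2[, 2]; m2$atoms$z <- X2[, 3]
    m2$centroid <- colMeans(X2)
    A <- best$T1
    Fr <- complete_frame(A)
    ext <- max(bbox_extent(rbind(X1, X2)))
    L <- cbind(A, (ext + 9) * Fr[1, ], (ext + 11) * Fr[2, ])
    contents <- contents_from_cartesian(id, list(host, m2), L,
                                        spacegroup_ops("P1"),
                                        spec$noise, spec$seed)
    truth <- c(truth, list(molecules_per_cell = 2, dimensionality = 1,
                           base_magnitudes = sqrt(sum(A^2)),
                           hbonds = tibble::tibble(
                             donor = c("N1", "N1B"),
                             acceptor = c("O1B", "O1"),
                             d_da = c(spec$d_da, spec$d_da))))
  }
  st <- crystal_structure(contents)
  dmin <- min_intermolecular_distance(st)
  if (dmin < 1.45) {
    stop("unrealizable spec: intermolecular clash at ",
         sprintf("%.2f", dmin), " Angstrom", call. = FALSE)
  }
  structure(list(contents = contents, truth = truth),
            class = "synthetic_crystal")
}

#' @export
print.synthetic_crystal <- function(x, ...) {
  cat(sprintf("<synthetic_crystal> %s (%s), %d site(s)\n",
              x$contents$structure_id, x$truth$kind, nrow(x$contents$sites)))
  invisible(x)
}

#' Build a comparison pair for a motif
#'
#' Generates the two structures whose pairwise comparison should recover the
#' motif: two independently noise-perturbed copies for most kinds, and a
#' substituent-swapped pair for `"isostructural_pair"`.
#'
#' @param kind Motif kind, see [motif_spec()].
#' @param seed Integer seed (the second copy uses `seed + 10000`).
#' @param noise Coordinate noise sigma in Angstrom.
#' @param ... Passed to [motif_spec()].
#' @return List with `structures` (two [crystal_structure()] objects) and
#'   `truth`.
#' @export
build_motif_pair <- function(kind, seed = 1, noise = 0.03, ...) {
  if (kind == "isostructural_pair") {
    s1 <- build_crystal(motif_spec(kind, noise = noise, seed = seed,
                                   substituent = "H", ...),
                        structure_id = "iso_H")
    s2 <- build_crystal(motif_spec(kind, noise = noise, seed = seed + 10000,
                                   substituent = "Cl", ...),
                        structure_id = "iso_Cl")
  } else {
    s1 <- build_crystal(motif_spec(kind, noise = noise, seed = seed, ...),
                        structure_id = paste0(kind, "_1"))
    s2 <- build_crystal(motif_spec(kind, noise = noise, seed = seed + 10000,
                                   ...),
                        structure_id = paste0(kind, "_2"))
  }
  list(structures = list(crystal_structure(s1$contents),
                         crystal_structure(s2$contents)),
       truth = s1$truth)
}

#' Build the engineered family fixture
#'
#' A deterministic family of toy structures sharing a hierarchy of motifs:
#' all dimer-based members share the 0D inversion dimer; three share a
#' 4.07-Angstrom dimer stack; two pairs share 13.4- and 18.6-Angstrom dimer
#' tapes; two members are fully isostructural; and two dimer-free members
#' share only an unrelated 12.4-Angstrom single-molecule tape (a second motif
#' lineage). Designed so family comparison reproduces the canonical
#' dependency pattern (3D set -> stack -> dimer; tapes -> dimer).
#'
#' @param noise Coordinate noise sigma in Angstrom.
#' @param seed Integer seed for the noise stream.
#' @return Named list of [crystal_structure()] objects (P, Q, R, S, T, U, V)
#'   with the construction targets attached as attribute `"truth"`.
#' @export
build_family_set <- function(noise = 0, seed = 1) {
  host_h <- make_toy_molecule("host", substituent = "H")
  host_cl <- make_toy_molecule("host", substituent = "Cl")
  m0 <- place_dimer_molecule(host_h, 2.87)
  m0cl <- place_dimer_molecule(host_cl, 2.87)
  dimer <- rbind(mol_xyz(m0), -mol_xyz(m0))
  el2 <- rep(host_h$atoms$element, 2)

  # ranked candidate directions per target magnitude (capped for the
  # backtracking search below)
  cap <- function(d, k = 20) d$dirs[seq_len(min(k, nrow(d$dirs))), , drop = FALSE]
  cand <- .synthetic_cache[["family_candidates"]]
  if (is.null(cand)) {
    cand <- list(
      s407 = cap(find_directions(dimer, 4.07, el2)),
      t134 = cap(find_directions(dimer, 13.4, el2)),
      t186 = cap(find_directions(dimer, 18.6, el2)),
      b124 = cap(find_directions(mol_xyz(host_h), 12.4,
                                 host_h$atoms$element)))
    .synthetic_cache[["family_candidates"]] <- cand
  }
  far <- function(axis1, axis2, len = 26) {
    n <- pracma_cross(axis1, axis2)
    len * n / sqrt(sum(n^2))
  }
  mk <- function(id, mol, L, sg = "P-1", sd) {
    contents <- contents_from_cartesian(id, list(mol), L, spacegroup_ops(sg),
                                        noise, sd)
    crystal_structure(contents)
  }
  # a candidate lattice is accepted only if the assembled crystal has the
  # expected molecule census and inter-molecular clearance survives noise
  ok <- function(st, n_expected, n_atoms) {
    length(st$polymeric) == 0 && length(st$molecules) == n_expected &&
      all(vapply(st$molecules, function(m) nrow(m$atoms),
                 integer(1)) == n_atoms) &&
      min_intermolecular_clearance(st) >= 0.5
  }
  ang_sep <- function(v, w) acos(min(1, abs(sum(v * w)))) * 180 / pi
  # base vectors are reported from a pairwise size-reduced generating set, so
  # the construction targets must already form a reduced (Lagrange) basis
  is_reduced <- function(L) {
    for (i in 1:ncol(L)) {
      for (j in 1:ncol(L)) {
        if (i != j &&
            round(sum(L[, i] * L[, j]) / sum(L[, i]^2)) != 0) return(FALSE)
      }
    }
    TRUE
  }

  # cheap whole-lattice feasibility: clearance of the repeat unit against
  # every nearby lattice-image combination (proper and inversion images)
  lat_ok <- function(L, unit, el) {
    grid <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
    inv_unit <- -unit
    for (r in seq_len(nrow(grid))) {
      n <- grid[r, ]
      v <- as.numeric(L %*% n)
      if (sqrt(sum(v^2)) > 30) next
      if (any(n != 0) &&
          !placement_ok(unit, el, sweep(unit, 2, v, "+"))) return(FALSE)
      if (!placement_ok(unit, el, sweep(inv_unit, 2, v, "+"),
                        lo = if (all(n == 0)) 0 else 1.7,
                        cov_margin = if (all(n == 0)) -99 else 0.55)) {
        return(FALSE)
      }
    }
    TRUE
  }

  key <- "family_geometry"
  geo <- .synthetic_cache[[key]]
  if (is.null(geo)) {
    xyz_h <- mol_xyz(m0)
    xyz_cl <- mol_xyz(m0cl)
    el1 <- host_h$atoms$element
    el1cl <- host_cl$atoms$element
    n407 <- nrow(cand$s407); n134 <- nrow(cand$t134); n186 <- nrow(cand$t186)
    geo <- local({
      # feasibility tables, then a cheap combinatorial search over them
      R_ok <- matrix(NA, n407, n134)
      S_ok <- matrix(NA, n134, n186)
      T_ok <- rep(NA, n186)
      chk_R <- function(i, j2) {
        if (is.na(R_ok[i, j2])) {
          A <- 4.07 * cand$s407[i, ]; B2 <- 13.4 * cand$t134[j2, ]
          R_ok[i, j2] <<- lat_ok(cbind(A, B2, far(A, B2)), xyz_h, el1)
        }
        R_ok[i, j2]
      }
      chk_S <- function(j2, k2) {
        if (is.na(S_ok[j2, k2])) {
          B2 <- 13.4 * cand$t134[j2, ]; C2 <- 18.6 * cand$t186[k2, ]
          S_ok[j2, k2] <<- lat_ok(cbind(far(B2, C2), B2, C2), xyz_h, el1)
        }
        S_ok[j2, k2]
      }
      chk_T <- function(k2) {
        if (is.na(T_ok[k2])) {
          C2 <- 18.6 * cand$t186[k2, ]
          FrT <- complete_frame(C2)
          T_ok[k2] <<- lat_ok(cbind(C2, 24 * FrT[1, ], 26 * FrT[2, ]),
                              xyz_h, el1)
        }
        T_ok[k2]
      }
      for (i in seq_len(n407)) {
        for (j in seq_len(n134)) {
          for (k in seq_len(n186)) {
            A <- 4.07 * cand$s407[i, ]
            B <- 13.4 * cand$t134[j, ]
            C <- 18.6 * cand$t186[k, ]
            L <- cbind(A, B, C)
            if (abs(det(L)) < 200) next
            if (!is_reduced(L)) next
            if (!lat_ok(L, xyz_h, el1) || !lat_ok(L, xyz_cl, el1cl)) next
            for (j2 in seq_len(n134)) {
              if (ang_sep(cand$t134[j2, ], cand$t134[j, ]) < 25) next
              if (!chk_R(i, j2)) next
              for (k2 in seq_len(n186)) {
                if (ang_sep(cand$t186[k2, ], cand$t186[k, ]) < 25) next
                if (!chk_S(j2, k2)) next
                if (!chk_T(k2)) next
                return(list(A = A, B = B, C = C,
                            B2 = 13.4 * cand$t134[j2, ],
                            C2 = 18.6 * cand$t186[k2, ]))
              }
            }
          }
        }
      }
      NULL
    })
    if (is.null(geo)) {
      stop("could not realize a clash-free family geometry", call. = FALSE)
    }
    # dimer-free tape lineage
    for (b in seq_len(nrow(cand$b124))) {
      B_U <- 12.4 * cand$b124[b, ]
      FrU <- complete_frame(B_U)
      U <- mk("U", host_h, cbind(B_U, 24 * FrU[1, ], 27 * FrU[2, ]), "P1",
              sd = 1)
      V <- mk("V", host_h, cbind(B_U, 25 * FrU[2, ], 28 * FrU[1, ]), "P1",
              sd = 1)
      if (ok(U, 1, 28) && ok(V, 1, 28)) {
        geo$B_U <- B_U
        break
      }
    }
    if (is.null(geo$B_U)) {
      stop("could not realize a clash-free dimer-free tape", call. = FALSE)
    }
    # verify the selected geometry on fully assembled crystals
    stopifnot(ok(mk("P", m0, cbind(geo$A, geo$B, geo$C), sd = 1), 1, 28),
              ok(mk("Q", m0cl, cbind(geo$A, geo$B, geo$C), sd = 1), 1, 28),
              ok(mk("R", m0, cbind(geo$A, geo$B2, far(geo$A, geo$B2)),
                    sd = 1), 1, 28),
              ok(mk("S", m0, cbind(far(geo$B2, geo$C2), geo$B2, geo$C2),
                    sd = 1), 1, 28))
    .synthetic_cache[[key]] <- geo
  }

  FrU <- complete_frame(geo$B_U)
  FrT <- complete_frame(geo$C2)
  sts <- list(
    P = mk("P", m0, cbind(geo$A, geo$B, geo$C), sd = seed + 1),
    Q = mk("Q", m0cl, cbind(geo$A, geo$B, geo$C), sd = seed + 2),
    R = mk("R", m0, cbind(geo$A, geo$B2, far(geo$A, geo$B2)), sd = seed + 3),
    S = mk("S", m0, cbind(far(geo$B2, geo$C2), geo$B2, geo$C2), sd = seed + 4),
    T = mk("T", m0, cbind(geo$C2, 24 * FrT[1, ], 26 * FrT[2, ]), sd = seed + 5),
    U = mk("U", host_h, cbind(geo$B_U, 24 * FrU[1, ], 27 * FrU[2, ]), "P1",
           sd = seed + 6),
    V = mk("V", host_h, cbind(geo$B_U, 25 * FrU[2, ], 28 * FrU[1, ]), "P1",
           sd = seed + 7))
  attr(sts, "truth") <- list(
    stack = 4.07, tape2 = 13.4, tape3 = 18.6, tape_b = 12.4,
    dependencies = c("A11->A01", "A12->A01", "A13->A01", "A31->A11"),
    members = list(A01 = c("P", "Q", "R", "S", "T"), A11 = c("P", "Q", "R"),
                   A12 = c("R", "S"), A13 = c("S", "T"), A31 = c("P", "Q"),
                   B11 = c("U", "V")))
  sts
}

# Smallest intermolecular (distance - covalent sum) over all symmetry images.
min_intermolecular_clearance <- function(structure) {
  best <- Inf
  for (mol in structure$molecules) {
    reach <- 2 * mol_radius(mol) + 6
    for (rec in enumerate_images(structure, mol$centroid, reach)) {
      if (same_image(rec, mol)) next
      best <- min(best, min_cov_clearance(
        mol_xyz(mol), mol$atoms$element,
        mol_xyz(rec$molecule), rec$molecule$atoms$element))
    }
  }
  best
}
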