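# Crystal model: symmetry expansion of the asymmetric unit, bond perception,
# assembly of chemically connected molecules in Cartesian space, disorder
# filtering and E/Z classification of exocyclic double bonds.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Perceive covalent bonds from Cartesian atoms
#'
#' Two atoms are bonded when their distance does not exceed the sum of their
#' covalent radii plus a tolerance. Hydrogen atoms never bond to each other
#' and keep only their single nearest heavy-atom bond.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (Cartesian
#'   Angstrom).
#' @param tolerance Bond-perception tolerance in Angstrom (default 0.40).
#' @return Two-column integer matrix of atom index pairs (i < j); zero rows
#'   when no bonds are found.
#' @export
perceive_bonds <- function(atoms, tolerance = 0.40) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  rc <- covalent_radius(atoms$element)
  cut <- outer(rc, rc, "+") + tolerance
  adj <- d <= cut & upper.tri(d)
  is_h <- atoms$element %in% c("H", "D")
  adj[is_h & rep(is_h, each = n)] <- FALSE   # no H-H
  pairs <- which(adj, arr.ind = TRUE)
  bonds <- cbind(i = pairs[, 1], j = pairs[, 2])
  # hydrogens: keep only the nearest heavy neighbour
  for (h in which(is_h)) {
    inv <- which(bonds[, 1] == h | bonds[, 2] == h)
    if (length(inv) > 1) {
      partners <- ifelse(bonds[inv, 1] == h, bonds[inv, 2], bonds[inv, 1])
      keep <- inv[which.min(d[h, partners])]
      bonds <- bonds[-setdiff(inv, keep), , drop = FALSE]
    }
  }
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

#' Keep the major conformer of disordered sites
#'
#' Within each disorder group -- sites with occupancy below 1 that either
#' overlap within 0.8 Angstrom or share a label stem (label with a trailing
#' conformer letter stripped) -- only the highest-occupancy alternative is
#' kept, with ties broken by label sort order.
#'
#' @param sites Site tibble (fractional coordinates, `occupancy` column).
#' @param cell A [unit_cell()] used to measure overlap in Angstrom.
#' @return The filtered site tibble; unchanged when all occupancies are 1.
#' @export
select_major_conformer <- function(sites, cell) {
  part <- which(sites$occupancy < 1)
  if (length(part) == 0) return(sites)
  cart <- frac_to_cart(cell, as.matrix(sites[part, c("x", "y", "z")]))
  if (length(part) == 1) return(sites)
  d <- as.matrix(stats::dist(cart))
  stem <- sub("[A-Za-z]$", "", sites$label[part])
  # union-find over the disorder-group relation
  parent <- seq_along(part)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(part)) {
    for (j in seq_along(part)) {
      if (i < j && (d[i, j] < 0.8 || stem[i] == stem[j])) {
        parent[find_root(j)] <- find_root(i)
      }
    }
  }
  roots <- vapply(seq_along(part), find_root, integer(1))
  drop <- integer(0)
  for (r in unique(roots)) {
    grp <- part[roots == r]
    if (length(grp) < 2) next
    ord <- order(-sites$occupancy[grp], sites$label[grp])
    drop <- c(drop, grp[ord[-1]])
  }
  if (length(drop)) sites[-drop, ] else sites
}

# Expand the asymmetric unit by all operators; wrap into [0,1); deduplicate
# special-position copies closer than dedup_tol Angstrom (same source site).
expand_sites <- function(contents, dedup_tol = 0.3) {
  M <- cell_orthomatrix(contents$cell)
  s <- contents$sites
  out <- list()
  for (k in seq_along(contents$ops)) {
    op <- contents$ops[[k]]
    f <- t(op$rot %*% t(as.matrix(s[, c("x", "y", "z")]))) +
      matrix(op$trans, nrow(s), 3, byrow = TRUE)
    f <- f %% 1
    out[[k]] <- tibble::tibble(site = seq_len(nrow(s)), label = s$label,
                               element = s$element, occupancy = s$occupancy,
                               op = k, fx = f[, 1], fy = f[, 2], fz = f[, 3])
  }
  ex <- dplyr::bind_rows(out)
  # periodic deduplication within each source site
  keep <- rep(TRUE, nrow(ex))
  for (si in unique(ex$site)) {
    idx <- which(ex$site == si)
    if (length(idx) < 2) next
    f <- as.matrix(ex[idx, c("fx", "fy", "fz")])
    for (a in seq_along(idx)[-1]) {
      for (b in seq_len(a - 1)) {
        if (!keep[idx[b]]) next
        df <- f[a, ] - f[b, ]
        df <- df - round(df)
        if (sqrt(sum((M %*% df)^2)) < dedup_tol) {
          keep[idx[a]] <- FALSE
          break
        }
      }
    }
  }
  ex[keep, ]
}

# Build the full-cell periodic bond list among expanded atoms: rows
# (i, j, sx, sy, sz) meaning atom i bonds to atom j shifted by the lattice
# vector (sx, sy, sz).
periodic_bonds <- function(ex, cell, tolerance = 0.40) {
  M <- cell_orthomatrix(cell)
  f <- as.matrix(ex[, c("fx", "fy", "fz")])
  n <- nrow(f)
  rc <- covalent_radius(ex$element)
  cut <- outer(rc, rc, "+") + tolerance
  is_h <- ex$element %in% c("H", "D")
  cut[is_h & rep(is_h, each = n)] <- -1
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  cart0 <- t(M %*% t(f))
  edges <- list()
  for (r in seq_len(nrow(shifts))) {
    sh <- shifts[r, ]
    cart_s <- t(M %*% t(f + matrix(sh, n, 3, byrow = TRUE)))
    d2 <- outer(rowSums(cart0^2), rowSums(cart_s^2), "+") -
      2 * tcrossprod(cart0, cart_s)
    d2[d2 < 0] <- 0
    hit <- which(sqrt(d2) <= cut & sqrt(d2) > 1e-6, arr.ind = TRUE)
    if (nrow(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(i = hit[, 1], j = hit[, 2],
              sx = sh[1], sy = sh[2], sz = sh[3])
    }
  }
  e <- do.call(rbind, edges)
  if (is.null(e)) e <- matrix(integer(0), ncol = 5)
  # hydrogen: single bond to the nearest heavy atom
  if (nrow(e)) {
    dlen <- sqrt(rowSums((t(M %*% t(f[e[, 2], , drop = FALSE] +
                                      e[, 3:5, drop = FALSE])) -
                            cart0[e[, 1], , drop = FALSE])^2))
    drop <- rep(FALSE, nrow(e))
    for (h in which(is_h)) {
      inv <- which(e[, 1] == h)
      if (length(inv) > 1) drop[setdiff(inv, inv[which.min(dlen[inv])])] <- TRUE
      # mirror edges j == h handled symmetrically below
    }
    e <- e[!drop, , drop = FALSE]
    # keep symmetry of the relation: retain (i,j,s) only if (j,i,-s) retained
    key <- paste(e[, 1], e[, 2], e[, 3], e[, 4], e[, 5])
    rkey <- paste(e[, 2], e[, 1], -e[, 3], -e[, 4], -e[, 5])
    e <- e[rkey %in% key, , drop = FALSE]
  }
  e
}

# Connected components of the periodic bond graph with lattice unwrapping.
# Returns a list of components, each with atom indices and integer offsets;
# components that cannot be unwrapped consistently are flagged polymeric.
unwrap_components <- function(ex, e) {
  n <- nrow(ex)
  comp <- rep(NA_integer_, n)
  offsets <- matrix(NA_real_, n, 3)
  adj <- split(seq_len(nrow(e)), e[, 1])
  comps <- list()
  cid <- 0L
  for (seed in seq_len(n)) {
    if (!is.na(comp[seed])) next
    cid <- cid + 1L
    comp[seed] <- cid
    offsets[seed, ] <- c(0, 0, 0)
    queue <- seed
    members <- seed
    polymeric <- FALSE
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (ei in adj[[as.character(u)]] %||% integer(0)) {
        v <- e[ei, 2]
        off <- offsets[u, ] + e[ei, 3:5]
        if (is.na(comp[v])) {
          comp[v] <- cid
          offsets[v, ] <- off
          queue <- c(queue, v)
          members <- c(members, v)
        } else if (comp[v] == cid && any(abs(offsets[v, ] - off) > 1e-6)) {
          polymeric <- TRUE
        }
      }
    }
    comps[[cid]] <- list(atoms = sort(members),
                         offsets = offsets[sort(members), , drop = FALSE],
                         polymeric = polymeric)
  }
  comps
}

make_molecule <- function(ex, cell, comp, bond_tolerance) {
  idx <- comp$atoms
  f <- as.matrix(ex[idx, c("fx", "fy", "fz")]) + comp$offsets
  cart <- frac_to_cart(cell, f)
  atoms <- tibble::tibble(label = ex$label[idx], element = ex$element[idx],
                          x = cart[, 1], y = cart[, 2], z = cart[, 3],
                          occupancy = ex$occupancy[idx])
  ord <- order(atoms$label)
  atoms <- atoms[ord, ]
  f <- f[ord, , drop = FALSE]
  bonds <- perceive_bonds(atoms, tolerance = bond_tolerance)
  mol <- list(atoms = atoms, fract = f, bonds = bonds,
              provenance = list(op = ex$op[idx][ord][1],
                                shift = as.integer(round(comp$offsets[ord[1], ]))),
              centroid = colMeans(cart[ord, , drop = FALSE]))
  class(mol) <- "molecule"
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms (%s), centroid (%.2f, %.2f, %.2f)\n",
              nrow(x$atoms), paste(sort(unique(x$atoms$element)), collapse = ""),
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

molecule_label_key <- function(mol) paste(sort(unique(mol$atoms$label)), collapse = "|")

#' Build a crystal structure model
#'
#' Expands the asymmetric unit by all symmetry operators, perceives covalent
#' bonds under periodic boundary conditions, unwraps connected components into
#' spatially contiguous molecules and keeps one representative per
#' symmetry-distinct molecule. Disordered sites are reduced to their major
#' conformer first; single oxygen atoms (with or without hydrogens) count as
#' water molecules. Components that cannot be unwrapped contiguously
#' (polymeric/catenated) are flagged and excluded from cluster analysis.
#'
#' @param contents A [cell_contents()] object (or CIF text/path via
#'   [parse_cif()]/[read_cif()]).
#' @param bond_tolerance Bond-perception tolerance in Angstrom.
#' @param keep_minor_conformers Keep all disorder components instead of the
#'   major conformer.
#' @return An object of class `crystal_structure` with fields `contents`,
#'   `cell`, `ortho` (orthogonalization matrix), `molecules` (representative
#'   [molecule][perceive_bonds] list), `n_images` (symmetry images of each
#'   representative per cell) and `polymeric` (flagged components).
#' @export
crystal_structure <- function(contents, bond_tolerance = 0.40,
                              keep_minor_conformers = FALSE) {
  stopifnot(inherits(contents, "cell_contents"))
  if (!keep_minor_conformers) {
    contents$sites <- select_major_conformer(contents$sites, contents$cell)
  }
  ex <- expand_sites(contents)
  e <- periodic_bonds(ex, contents$cell, tolerance = bond_tolerance)
  comps <- unwrap_components(ex, e)
  polymeric <- Filter(function(cc) cc$polymeric, comps)
  comps <- Filter(function(cc) !cc$polymeric, comps)
  mols <- lapply(comps, make_molecule, ex = ex, cell = contents$cell,
                 bond_tolerance = bond_tolerance)
  # group symmetry images by their site-label set; pick a deterministic
  # representative (prefer identity-operator images, then smallest offset)
  keys <- vapply(mols, molecule_label_key, character(1))
  reps <- list()
  n_images <- integer(0)
  for (k in sort(unique(keys))) {
    grp <- mols[keys == k]
    score <- vapply(grp, function(m) {
      m$provenance$op * 1e6 + sum(abs(m$provenance$shift)) * 1e3 +
        sum(abs(m$centroid)) / 1e3
    }, numeric(1))
    reps[[length(reps) + 1L]] <- grp[[which.min(score)]]
    n_images <- c(n_images, length(grp))
  }
  structure(list(contents = contents, cell = contents$cell,
                 ortho = cell_orthomatrix(contents$cell),
                 molecules = reps, n_images = n_images,
                 bond_tolerance = bond_tolerance,
                 polymeric = polymeric),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %s: %d symmetry-distinct molecule(s), %d operator(s)\n",
              x$contents$structure_id, length(x$molecules),
              length(x$contents$ops)))
  print(x$cell)
  invisible(x)
}

#' Symmetry-distinct molecules of a structure
#'
#' @param structure A [crystal_structure()].
#' @return List of molecule objects (one representative per symmetry-distinct
#'   molecule).
#' @export
molecules <- function(structure) structure$molecules

# The main (largest) molecule -- the host in hydrates; ties broken by label key.
host_molecule <- function(structure) {
  mols <- structure$molecules
  sizes <- vapply(mols, function(m) nrow(m$atoms), integer(1))
  keys <- vapply(mols, molecule_label_key, character(1))
  mols[[order(-sizes, keys)[1]]]
}

# Apply (operator k, lattice shift n) to a molecule; returns the image
# molecule with provenance recorded relative to the representative.
molecule_image <- function(structure, mol, op_index, shift = c(0L, 0L, 0L)) {
  op <- structure$contents$ops[[op_index]]
  f <- t(op$rot %*% t(mol$fract)) +
    matrix(op$trans + shift, nrow(mol$fract), 3, byrow = TRUE)
  cart <- frac_to_cart(structure$cell, f)
  img <- mol
  img$fract <- f
  img$atoms$x <- cart[, 1]
  img$atoms$y <- cart[, 2]
  img$atoms$z <- cart[, 3]
  img$centroid <- colMeans(cart)
  img$provenance <- list(op = op_index, shift = as.integer(shift))
  img
}

#' Classify the geometry of an exocyclic C=C bond as E or Z
#'
#' Computes the torsion angle reference1--atom1=atom2--reference2 and labels
#' the configuration `"Z"` when the torsion lies within (-90, 90) degrees
#' (synperiplanar references) and `"E"` otherwise. For the methylidene
#' oxindoles the conventional references are the ring carbonyl carbon on the
#' oxindole side and the ipso aryl carbon on the benzylidene side.
#'
#' @param molecule A molecule object.
#' @param bond Character vector of two atom labels: the double-bond atoms.
#' @param refs Character vector of two atom labels: the reference substituent
#'   on each double-bond atom, in the same order as `bond`.
#' @return `"E"` or `"Z"`, with the torsion angle (degrees) as attribute
#'   `"torsion"`.
#' @export
classify_cc_geometry <- function(molecule, bond, refs) {
  lbl <- molecule$atoms$label
  need <- c(refs[1], bond, refs[2])
  miss <- setdiff(need, lbl)
  if (length(miss)) {
    stop("reference/bond atom(s) missing from molecule: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- as.matrix(molecule$atoms[match(need, lbl), c("x", "y", "z")])
  tor <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  structure(if (abs(tor) <= 90) "Z" else "E", torsion = tor)
}
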