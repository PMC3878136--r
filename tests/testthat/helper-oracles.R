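# Independent brute-force oracles and small fixture builders shared by the
# suite. The oracles deliberately re-derive quantities from first principles
# (plain nested loops over all symmetry/translation images) so they share no
# code path with the package implementations they check.

# All expanded atom positions (Cartesian) of a structure over ops x shifts.
all_image_atoms <- function(st, window = 3) {
  ops <- st$contents$ops
  s <- st$contents$sites
  M <- cell_orthomatrix(st$cell)
  out <- list()
  for (k in seq_along(ops)) {
    f0 <- t(ops[[k]]$rot %*% t(as.matrix(s[, c("x", "y", "z")]))) +
      matrix(ops[[k]]$trans, nrow(s), 3, byrow = TRUE)
    for (sx in -window:window) for (sy in -window:window) for (sz in -window:window) {
      f <- f0 + matrix(c(sx, sy, sz), nrow(s), 3, byrow = TRUE)
      cart <- t(M %*% t(f))
      out[[length(out) + 1L]] <- data.frame(
        label = s$label, element = s$element, op = k,
        sx = sx, sy = sy, sz = sz,
        x = cart[, 1], y = cart[, 2], z = cart[, 3])
    }
  }
  do.call(rbind, out)
}

# Brute-force hydrogen-bond enumeration: all D-H...A triples over all images,
# canonicalized to a set of (donor, acceptor, d, angle) keys.
oracle_hbond_keys <- function(st, max_da = 3.5, min_angle = 120,
                              window = 2) {
  img <- all_image_atoms(st, window)
  keys <- character(0)
  for (mol in st$molecules) {
    at <- mol$atoms
    don <- which(at$element %in% c("N", "O"))
    for (di in don) {
      D <- c(at$x[di], at$y[di], at$z[di])
      hs <- integer(0)
      for (hi in which(at$element %in% c("H", "D"))) {
        H <- c(at$x[hi], at$y[hi], at$z[hi])
        if (sqrt(sum((D - H)^2)) <=
            covalent_radius(at$element[di]) + covalent_radius("H") + 0.40) {
          hs <- c(hs, hi)
        }
      }
      acc <- which(img$element %in% c("N", "O"))
      for (ai in acc) {
        A <- c(img$x[ai], img$y[ai], img$z[ai])
        dda <- sqrt(sum((D - A)^2))
        if (dda > max_da || dda < 1e-3) next
        # skip acceptors inside the donor's own molecule image
        own <- any(abs(at$x - A[1]) < 1e-6 & abs(at$y - A[2]) < 1e-6 &
                     abs(at$z - A[3]) < 1e-6)
        if (own) next
        for (hi in hs) {
          H <- c(at$x[hi], at$y[hi], at$z[hi])
          v1 <- D - H
          v2 <- A - H
          ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= min_angle) {
            keys <- c(keys, paste(at$label[di], img$label[ai],
                                  round(dda, 3), round(ang, 1)))
          }
        }
      }
    }
  }
  sort(unique(keys))
}

# Brute-force close contacts: atom pairs below vdW sum + margin between a
# representative molecule and every image, canonical unordered keys.
oracle_contact_keys <- function(st, margin = 0, window = 2) {
  img <- all_image_atoms(st, window)
  keys <- character(0)
  for (mol in st$molecules) {
    at <- mol$atoms
    for (i in seq_len(nrow(at))) {
      P <- c(at$x[i], at$y[i], at$z[i])
      for (j in seq_len(nrow(img))) {
        A <- c(img$x[j], img$y[j], img$z[j])
        d <- sqrt(sum((P - A)^2))
        if (d < 1e-3) next
        vs <- vdw_radius(at$element[i]) + vdw_radius(img$element[j])
        if (d >= vs + margin) next
        # exclude pairs within the same molecule image: the image must not
        # coincide with the representative's own atoms
        own <- all(vapply(seq_len(nrow(at)), function(q) {
          any(abs(img$x - at$x[q]) < 1e-6 & abs(img$y - at$y[q]) < 1e-6 &
                abs(img$z - at$z[q]) < 1e-6 &
                img$op == img$op[j] & img$sx == img$sx[j] &
                img$sy == img$sy[j] & img$sz == img$sz[j] &
                img$label == at$label[q])
        }, logical(1)))
        if (own) next
        lb <- sort(c(at$label[i], img$label[j]))
        keys <- c(keys, paste(lb[1], lb[2], round(d, 3)))
      }
    }
  }
  sort(unique(keys))
}

# Brute-force coordination shell: centroids of every image molecule with an
# atom within vdW sum + margin of the kernel, as a sorted distance multiset.
oracle_shell_distances <- function(st, margin = 1.5, window = 2) {
  kern <- packmotif:::host_molecule(st)
  kxyz <- as.matrix(kern$atoms[, c("x", "y", "z")])
  M <- cell_orthomatrix(st$cell)
  ops <- st$contents$ops
  dists <- numeric(0)
  seen <- character(0)
  for (mol in st$molecules) {
    for (k in seq_along(ops)) {
      for (sx in -window:window) for (sy in -window:window) for (sz in -window:window) {
        f <- t(ops[[k]]$rot %*% t(mol$fract)) +
          matrix(ops[[k]]$trans + c(sx, sy, sz), nrow(mol$fract), 3,
                 byrow = TRUE)
        cart <- t(M %*% t(f))
        key <- paste(round(cart[order(mol$atoms$label), ], 3), collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        cd <- sqrt(sum((colMeans(cart) - kern$centroid)^2))
        if (cd < 1e-6 &&
            packmotif:::molecule_label_key(mol) ==
            packmotif:::molecule_label_key(kern)) next
        dmat <- sqrt(outer(rowSums(kxyz^2), rowSums(cart^2), "+") -
                       2 * tcrossprod(kxyz, cart))
        cut <- outer(vdw_radius(kern$atoms$element),
                     vdw_radius(mol$atoms$element), "+") + margin
        if (any(dmat <= cut)) dists <- c(dists, cd)
      }
    }
  }
  sort(round(dists, 5))
}

# Random small P-1 structure: one rigid random molecule of n_atoms in a
# roomy triclinic cell, placed off the inversion centers so assembly keeps
# it whole and unwrapped. Seeds yielding fused/wrapped molecules are
# deterministically re-drawn.
random_small_structure <- function(seed, n_atoms = 5) {
  draw <- function(s) {
    set.seed(s)
    elements <- sample(c("C", "N", "O"), n_atoms, replace = TRUE)
    xyz <- matrix(0, n_atoms, 3)
    for (i in seq_len(n_atoms - 1)) {
      step <- rnorm(3)
      step <- step / sqrt(sum(step^2)) * 1.45
      xyz[i + 1, ] <- xyz[i, ] + step
    }
    cell <- unit_cell(12 + runif(1, 0, 3), 13 + runif(1, 0, 3),
                      14 + runif(1, 0, 3),
                      85 + runif(1, 0, 10), 85 + runif(1, 0, 10),
                      85 + runif(1, 0, 10))
    ops <- lapply(c("x, y, z", "-x, -y, -z"), parse_symop)
    offset <- frac_to_cart(cell, c(0.27, 0.29, 0.26)) - colMeans(xyz)
    f <- cart_to_frac(cell, sweep(xyz, 2, offset, "+"))
    sites <- tibble::tibble(label = paste0(elements, seq_len(n_atoms)),
                            element = elements,
                            x = f[, 1], y = f[, 2], z = f[, 3], occupancy = 1)
    crystal_structure(cell_contents(paste0("rand", s), cell, ops, sites))
  }
  s <- seed
  for (try in 1:20) {
    st <- draw(s)
    whole <- length(st$molecules) == 1 &&
      nrow(st$molecules[[1]]$atoms) == n_atoms &&
      all(st$molecules[[1]]$fract > 0 & st$molecules[[1]]$fract < 1)
    if (whole) return(st)
    s <- s * 31 + 7
  }
  stop("could not draw a valid random fixture from seed ", seed)
}

# Minimal CIF documents used across the CIF tests.
minimal_p1_cif <- function() {
  c("data_min",
    "_cell_length_a 10.0", "_cell_length_b 10.0", "_cell_length_c 10.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x, y, z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.0 0.0 0.0")
}

rigid_transform <- function(xyz, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  sweep(xyz %*% t(R), 2, rnorm(3, 0, 5), "+")
}
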