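# Packing-similarity engine: local-frame pair descriptors, tolerance-based
# cluster matching, dimensionality and base vectors of shared motifs.

# --- rigid-body helpers ----------------------------------------------------

# Best proper rotation R such that R %*% t(src) ~ t(dst) (both centered).
kabsch_rotation <- function(src, dst) {
  H <- t(src) %*% dst
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

quat_from_rotation <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

# Angular distance between two unit quaternions, in degrees.
quat_angle <- function(q1, q2) {
  2 * acos(min(1, abs(sum(q1 * q2)))) * 180 / pi
}

vec_angle <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Orthonormal local frame of an ordered point set: principal axes of the
# centered points (noise-averaged over every correspondence point, so the
# frame is far more stable than one built from a single atom triple), with
# deterministic sign fixing (largest-magnitude component positive) and a
# right-handed third axis.
local_frame <- function(pts) {
  if (nrow(pts) < 3) stop("frame needs >= 3 points", call. = FALSE)
  X <- sweep(pts, 2, colMeans(pts))
  sv <- svd(X)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1)) {
    stop("correspondence points are collinear", call. = FALSE)
  }
  V <- sv$v
  # intrinsic sign convention: each axis points towards the correspondence
  # point with the largest projection on it (stable under noise, independent
  # of the global orientation of the model)
  for (j in 1:2) {
    proj <- X %*% V[, j]
    if (proj[which.max(abs(proj))] < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- pracma_cross(V[, 1], V[, 2])
  V
}

# --- correspondence --------------------------------------------------------

#' Correspondence set between two structures' host molecules
#'
#' With `selection = "auto"` the correspondence is the intersection of
#' non-hydrogen atom labels shared by the host molecules, ordered
#' lexicographically; an explicit label vector overrides. At least three
#' non-collinear points are required.
#'
#' @param struct_a,struct_b [crystal_structure()] objects.
#' @param selection `"auto"` or a character vector of atom labels.
#' @return Character vector of labels, class `correspondence`.
#' @export
make_correspondence <- function(struct_a, struct_b, selection = "auto") {
  ha <- host_molecule(struct_a)
  hb <- host_molecule(struct_b)
  if (identical(selection, "auto")) {
    la <- ha$atoms$label[!ha$atoms$element %in% c("H", "D")]
    lb <- hb$atoms$label[!hb$atoms$element %in% c("H", "D")]
    sel <- sort(intersect(la, lb))
  } else {
    sel <- as.character(selection)
    miss <- setdiff(sel, intersect(ha$atoms$label, hb$atoms$label))
    if (length(miss)) {
      stop("correspondence labels missing from one structure: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  if (length(sel) < 3) {
    stop("fewer than 3 usable correspondence points", call. = FALSE)
  }
  pts <- as.matrix(ha$atoms[match(sel, ha$atoms$label), c("x", "y", "z")])
  local_frame(pts)  # errors if collinear
  structure(sel, class = "correspondence")
}

corr_points <- function(mol, corr) {
  idx <- match(as.character(corr), mol$atoms$label)
  if (anyNA(idx)) return(NULL)
  as.matrix(mol$atoms[idx, c("x", "y", "z")])
}

# --- pair descriptors ------------------------------------------------------

#' Geometric descriptor of a kernel-to-neighbour molecule pair
#'
#' Describes the placement of one shell molecule relative to the kernel, in
#' the kernel's local orthonormal frame (built from the ordered correspondence
#' points), so the descriptor is invariant under rigid motion of the whole
#' crystal model: `d` -- distance between correspondence centroids; `u` --
#' unit centroid-offset direction in the kernel frame; `quat` -- unit
#' quaternion of the best proper superposition of the neighbour
#' correspondence points onto the kernel's (improper, i.e. inversion- or
#' mirror-related, neighbours are inverted through their centroid first and
#' flagged by the parity bit); `translation` -- whether the generating
#' operator is a pure lattice translation, with the total fractional
#' translation attached.
#'
#' @param cluster A [build_cluster()] result.
#' @param shell_index Index into the cluster shell.
#' @param corr A [make_correspondence()] set.
#' @return List of class `pair_descriptor`.
#' @export
pair_descriptor <- function(cluster, shell_index, corr) {
  kpts <- corr_points(cluster$kernel, corr)
  if (is.null(kpts)) stop("kernel lacks correspondence points", call. = FALSE)
  rec <- cluster$shell[[shell_index]]
  spts <- corr_points(rec$molecule, corr)
  if (is.null(spts)) {
    stop("shell molecule ", shell_index, " lacks correspondence points",
         call. = FALSE)
  }
  op <- cluster$structure$contents$ops[[rec$op]]
  improper <- round(det(op$rot)) < 0
  rot_key <- paste(op$rot, collapse = ",")
  t_total <- op$trans + rec$shift
  Fk <- local_frame(kpts)
  ck <- colMeans(kpts)
  cs <- colMeans(spts)
  offset <- as.numeric(t(Fk) %*% (cs - ck))
  d <- sqrt(sum(offset^2))
  u <- if (d > 1e-9) offset / d else c(1, 0, 0)
  kl <- t(t(Fk) %*% t(sweep(kpts, 2, ck)))
  sl <- t(t(Fk) %*% t(sweep(spts, 2, cs)))
  if (improper) sl <- -sl
  R <- kabsch_rotation(sl, kl)
  translation <- symop_is_translation(op)
  structure(list(d = d, u = u, quat = quat_from_rotation(R),
                 improper = improper, translation = translation,
                 rot_key = rot_key, t_total = t_total,
                 shell_index = shell_index),
            class = "pair_descriptor")
}

cluster_descriptors <- function(cluster, corr) {
  out <- list()
  for (i in seq_along(cluster$shell)) {
    if (is.null(corr_points(cluster$shell[[i]]$molecule, corr))) next
    out[[length(out) + 1L]] <- pair_descriptor(cluster, i, corr)
  }
  out
}

desc_tibble <- function(descs) {
  if (length(descs) == 0) {
    return(tibble::tibble(shell_index = integer(0), d = numeric(0),
                          ux = numeric(0), uy = numeric(0), uz = numeric(0),
                          q1 = numeric(0), q2 = numeric(0), q3 = numeric(0),
                          q4 = numeric(0), improper = logical(0),
                          translation = logical(0), rot_key = character(0),
                          tx = numeric(0), ty = numeric(0), tz = numeric(0)))
  }
  dplyr::bind_rows(lapply(descs, function(p) {
    tibble::tibble(shell_index = p$shell_index, d = p$d,
                   ux = p$u[1], uy = p$u[2], uz = p$u[3],
                   q1 = p$quat[1], q2 = p$quat[2], q3 = p$quat[3],
                   q4 = p$quat[4], improper = p$improper,
                   translation = p$translation, rot_key = p$rot_key,
                   tx = p$t_total[1], ty = p$t_total[2], tz = p$t_total[3])
  }))
}

# deviation between two descriptor rows (lists with d, u, quat, flags);
# Inf when incompatible.
desc_deviation <- function(a, b, tol_d, tol_ang) {
  if (a$improper != b$improper || a$translation != b$translation) return(Inf)
  dd <- abs(a$d - b$d)
  if (dd > tol_d) return(Inf)
  du <- vec_angle(a$u, b$u)
  if (du > tol_ang) return(Inf)
  dq <- quat_angle(a$quat, b$quat)
  if (dq > tol_ang) return(Inf)
  (dd / tol_d + du / tol_ang + dq / tol_ang) / 3
}

# --- matching --------------------------------------------------------------

#' Match two coordination clusters within tolerances
#'
#' Finds a maximal one-to-one assignment of shell members of two clusters
#' such that paired members agree in centroid distance (within `tol_d`),
#' offset direction and superposition rotation (within `tol_ang`) and parity.
#' Assignment is greedy by ascending combined deviation with a deterministic
#' provenance tie-break. Shell members lacking the correspondence points
#' (e.g. solvent) are skipped.
#'
#' @param cluster_a,cluster_b [build_cluster()] results.
#' @param corr A [make_correspondence()] set valid in both structures.
#' @param tol_d Distance tolerance in Angstrom (default 0.5).
#' @param tol_ang Angular tolerance in degrees (default 12), applied to both
#'   the quaternion distance and the offset-direction angle.
#' @return A tibble of matched pairs (class `cluster_match`): shell indices
#'   `a`/`b`, deviations, parity/translation flags and the fractional lattice
#'   translations of pure-translation pairs; descriptors and clusters are
#'   attached as attributes.
#' @export
match_clusters <- function(cluster_a, cluster_b, corr, tol_d = 0.5,
                           tol_ang = 12) {
  da <- cluster_descriptors(cluster_a, corr)
  db <- cluster_descriptors(cluster_b, corr)
  cand <- list()
  for (i in seq_along(da)) {
    for (j in seq_along(db)) {
      dev <- desc_deviation(da[[i]], db[[j]], tol_d, tol_ang)
      if (is.finite(dev)) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j, dev = dev)
      }
    }
  }
  rows <- list()
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, "dev"], cm[, "i"], cm[, "j"]), , drop = FALSE]
    used_a <- logical(length(da))
    used_b <- logical(length(db))
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      pa <- da[[i]]; pb <- db[[j]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        a = pa$shell_index, b = pb$shell_index,
        dd = abs(pa$d - pb$d), du = vec_angle(pa$u, pb$u),
        dq = quat_angle(pa$quat, pb$quat), dev = cm[r, "dev"],
        improper = pa$improper, translation = pa$translation,
        rka = pa$rot_key, rkb = pb$rot_key,
        tax = pa$t_total[1], tay = pa$t_total[2], taz = pa$t_total[3],
        tbx = pb$t_total[1], tby = pb$t_total[2], tbz = pb$t_total[3],
        d_a = pa$d, d_b = pb$d)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(a = integer(0), b = integer(0), dd = numeric(0),
                   du = numeric(0), dq = numeric(0), dev = numeric(0),
                   improper = logical(0), translation = logical(0),
                   rka = character(0), rkb = character(0),
                   tax = numeric(0), tay = numeric(0), taz = numeric(0),
                   tbx = numeric(0), tby = numeric(0), tbz = numeric(0),
                   d_a = numeric(0), d_b = numeric(0))
  }
  out <- dplyr::arrange(out, .data$dev, .data$a, .data$b)
  attr(out, "desc_a") <- da
  attr(out, "desc_b") <- db
  attr(out, "cluster_a") <- cluster_a
  attr(out, "cluster_b") <- cluster_b
  attr(out, "tol") <- c(d = tol_d, ang = tol_ang)
  class(out) <- c("cluster_match", class(out))
  out
}

#' Normalized dissimilarity of a matched pair set
#'
#' Root-mean-square of the tolerance-normalized deviations (|delta d|/tol_d
#' and the two angular deviations/tol_ang) over all matched pairs: 0 for
#' exact self-comparison, at most 1 when every accepted pair sits on the
#' tolerance boundary.
#'
#' @param match A [match_clusters()] result with at least one matched pair.
#' @return Non-negative scalar.
#' @export
dissimilarity_index <- function(match) {
  if (nrow(match) == 0) {
    stop("dissimilarity index is undefined for an empty match", call. = FALSE)
  }
  tol <- attr(match, "tol")
  sqrt(mean(c((match$dd / tol["d"])^2, (match$du / tol["ang"])^2,
              (match$dq / tol["ang"])^2)))
}

# --- lattice span of matched translations ---------------------------------

# Integer row Hermite-style reduction of translation vectors (components in
# 1/2-integers to accommodate lattice centerings). Returns a generating set.
translation_basis <- function(tmat) {
  if (nrow(tmat) == 0) return(matrix(numeric(0), 0, 3))
  m <- round(tmat * 2)
  m <- m[rowSums(abs(m)) > 0, , drop = FALSE]
  if (nrow(m) == 0) return(matrix(numeric(0), 0, 3))
  # integer row echelon via gcd elimination
  basis <- matrix(0, 0, 3)
  for (r in seq_len(nrow(m))) {
    v <- m[r, ]
    if (nrow(basis) > 0) {
      for (b in seq_len(nrow(basis))) {
        piv <- which(basis[b, ] != 0)[1]
        while (v[piv] != 0) {
          q <- v[piv] %/% basis[b, piv]
          v <- v - q * basis[b, ]
          if (v[piv] != 0) {
            tmp <- basis[b, ]; basis[b, ] <- v; v <- tmp
          }
        }
      }
    }
    if (any(v != 0)) {
      basis <- rbind(basis, v)
      # keep rows ordered by pivot column
      piv <- apply(basis, 1, function(x) which(x != 0)[1])
      basis <- basis[order(piv), , drop = FALSE]
    }
  }
  basis / 2
}

# Size-reduce a fractional basis against the cell metric so reported base
# vectors are the short generators (Lagrange-style pair reduction).
size_reduce_basis <- function(basis, cell) {
  if (nrow(basis) < 2) return(basis)
  M <- cell_orthomatrix(cell)
  norm2 <- function(v) sum((M %*% v)^2)
  repeat {
    changed <- FALSE
    ord <- order(apply(basis, 1, norm2))
    basis <- basis[ord, , drop = FALSE]
    for (i in seq_len(nrow(basis))) {
      for (j in seq_len(nrow(basis))) {
        if (i == j) next
        num <- sum((M %*% basis[j, ]) * (M %*% basis[i, ]))
        mu <- round(num / norm2(basis[i, ]))
        if (mu != 0) {
          cand <- basis[j, ] - mu * basis[i, ]
          if (norm2(cand) < norm2(basis[j, ]) - 1e-9) {
            basis[j, ] <- cand
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  basis[order(apply(basis, 1, norm2)), , drop = FALSE]
}

#' Dimensionality and base vectors of a matched motif
#'
#' Collects the matched shell members related to the kernel by pure lattice
#' translation in both structures, reduces those translations to a generating
#' set of the translation sublattice, and reports its rank as the motif
#' dimensionality: 0D for discrete assemblies (matches but no translations),
#' 1D for rows/stacks, 2D for layers, 3D for isostructural packings.
#'
#' @param match A [match_clusters()] result.
#' @details The motif's translation sublattice is generated not only by
#'   matched shell members that are themselves pure lattice translates of the
#'   kernel, but by the provenance differences of every pair of matched
#'   members sharing the same operator rotation in both structures (the
#'   kernel, which always matches, counts as a member): a dimer tape, for
#'   example, exposes its repeat vector through two inversion-related
#'   neighbours one lattice step apart even when the kernel's own translate
#'   is out of contact range.
#' @return List of class `motif_dimensionality`: `dimensionality` (0-3),
#'   `basis_frac` (generating translations, fractional, structure A),
#'   `magnitudes` (Angstrom, structure A cell), `magnitudes_b` (same
#'   generators measured in structure B's cell).
#' @export
derive_dimensionality <- function(match) {
  if (nrow(match) == 0) stop("empty match list", call. = FALSE)
  cl_a <- attr(match, "cluster_a")
  cl_b <- attr(match, "cluster_b")
  id_key <- paste(diag(3), collapse = ",")
  rka <- c(id_key, match$rka)
  rkb <- c(id_key, match$rkb)
  ta <- rbind(c(0, 0, 0), as.matrix(match[, c("tax", "tay", "taz")]))
  tb <- rbind(c(0, 0, 0), as.matrix(match[, c("tbx", "tby", "tbz")]))
  da <- list()
  db <- list()
  n <- length(rka)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (rka[i] != rka[j] || rkb[i] != rkb[j]) next
      da[[length(da) + 1L]] <- ta[i, ] - ta[j, ]
      db[[length(db) + 1L]] <- tb[i, ] - tb[j, ]
    }
  }
  tra <- if (length(da)) do.call(rbind, da) else matrix(numeric(0), 0, 3)
  trb <- if (length(db)) do.call(rbind, db) else matrix(numeric(0), 0, 3)
  basis <- size_reduce_basis(translation_basis(tra), cl_a$structure$cell)
  basis_b <- size_reduce_basis(translation_basis(trb), cl_b$structure$cell)
  mags <- if (nrow(basis)) {
    unname(sqrt(rowSums(frac_to_cart(cl_a$structure$cell, basis)^2)))
  } else numeric(0)
  mags_b <- if (nrow(basis_b)) {
    unname(sqrt(rowSums(frac_to_cart(cl_b$structure$cell, basis_b)^2)))
  } else numeric(0)
  structure(list(dimensionality = nrow(basis), basis_frac = basis,
                 magnitudes = mags, magnitudes_b = mags_b),
            class = "motif_dimensionality")
}

#' @export
print.motif_dimensionality <- function(x, ...) {
  cat(sprintf("<motif> %dD", x$dimensionality))
  if (length(x$magnitudes)) {
    cat(", base vectors ", paste(sprintf("%.3f", sort(x$magnitudes)),
                                 collapse = ", "), " A", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Compare the packing of two crystal structures
#'
#' Convenience wrapper: builds host-kernel clusters, derives the automatic
#' correspondence, matches them and reports the motif dimensionality.
#'
#' @param struct_a,struct_b [crystal_structure()] objects.
#' @param corr `"auto"` or a label vector, see [make_correspondence()].
#' @param tol_d,tol_ang Matching tolerances, see [match_clusters()].
#' @param margin Cluster contact margin in Angstrom.
#' @param include_waters Keep solvent molecules in the cluster shells.
#' @return List of class `packing_comparison`: `match`, `motif`
#'   (dimensionality + base vectors, `NULL` when nothing matches),
#'   `dissimilarity`, and the two structure ids.
#' @export
compare_structures <- function(struct_a, struct_b, corr = "auto", tol_d = 0.5,
                               tol_ang = 12, margin = 1.5,
                               include_waters = TRUE) {
  correspondence <- if (inherits(corr, "correspondence")) corr else {
    make_correspondence(struct_a, struct_b, corr)
  }
  cl_a <- build_cluster(struct_a, margin = margin,
                        include_waters = include_waters)
  cl_b <- build_cluster(struct_b, margin = margin,
                        include_waters = include_waters)
  m <- match_clusters(cl_a, cl_b, correspondence, tol_d = tol_d,
                      tol_ang = tol_ang)
  motif <- if (nrow(m) > 0) derive_dimensionality(m) else NULL
  structure(list(id_a = struct_a$contents$structure_id,
                 id_b = struct_b$contents$structure_id,
                 match = m, motif = motif,
                 dissimilarity = if (nrow(m)) dissimilarity_index(m) else NA_real_,
                 correspondence = correspondence),
            class = "packing_comparison")
}

#' @export
print.packing_comparison <- function(x, ...) {
  cat(sprintf("<packing_comparison> %s vs %s: %d matched pair(s)\n",
              x$id_a, x$id_b, nrow(x$match)))
  if (!is.null(x$motif)) print(x$motif)
  invisible(x)
}
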