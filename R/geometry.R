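# Per-structure geometry: hydrogen bonds, sub-van-der-Waals close contacts,
# least-squares mean planes, interplanar and torsion angles.

#' Torsion angle of four points
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian points.
#' @return Signed torsion angle in degrees in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares mean plane through a point set
#'
#' The plane minimizing the sum of squared perpendicular distances, obtained
#' from the singular value decomposition of the centered coordinates. The
#' normal is oriented so its first non-zero component is positive.
#'
#' @param points An n x 3 matrix or a data frame with columns `x`, `y`, `z`;
#'   n >= 3 non-collinear points.
#' @return List of class `mean_plane` with `normal` (unit), `centroid` and
#'   `rms` (root-mean-square perpendicular deviation in Angstrom).
#' @export
mean_plane <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  stopifnot(is.matrix(points), ncol(points) == 3)
  n <- nrow(points)
  if (n < 3) stop("mean plane needs at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("points are collinear; mean plane is degenerate", call. = FALSE)
  }
  normal <- sv$v[, 3]
  nz <- which(abs(normal) > 1e-12)[1]
  if (normal[nz] < 0) normal <- -normal
  structure(list(normal = normal, centroid = ctr, rms = sv$d[3] / sqrt(n)),
            class = "mean_plane")
}

#' @export
print.mean_plane <- function(x, ...) {
  cat(sprintf("<mean_plane> normal (%.4f, %.4f, %.4f), rms %.4f A\n",
              x$normal[1], x$normal[2], x$normal[3], x$rms))
  invisible(x)
}

#' Acute angle between two mean planes
#'
#' @param p1,p2 [mean_plane()] objects.
#' @return Angle in degrees in \code{[0, 90]}, invariant under normal sign
#'   flips.
#' @export
interplanar_angle <- function(p1, p2) {
  d <- abs(sum(p1$normal * p2$normal))
  acos(min(1, d)) * 180 / pi
}

# --- symmetry image enumeration -------------------------------------------

# Perpendicular spacings of the three lattice-plane families (A).
lattice_spacings <- function(cell) {
  M <- cell_orthomatrix(cell)
  v <- cell_volume(cell)
  areas <- c(sqrt(sum(pracma_cross(M[, 2], M[, 3])^2)),
             sqrt(sum(pracma_cross(M[, 3], M[, 1])^2)),
             sqrt(sum(pracma_cross(M[, 1], M[, 2])^2)))
  v / areas
}

mol_radius <- function(mol) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  sqrt(max(rowSums(sweep(xyz, 2, mol$centroid)^2)))
}

# All symmetry/translation images of the representative molecules whose
# centroid lies within `reach` of `center`. Returns a list of records
# (mol_id, op, shift, molecule). `min_window` forces at least that translation
# range per axis.
enumerate_images <- function(structure, center, reach, min_window = 2L) {
  sp <- lattice_spacings(structure$cell)
  out <- list()
  for (mi in seq_along(structure$molecules)) {
    mol <- structure$molecules[[mi]]
    r <- mol_radius(mol)
    w <- pmax(min_window, ceiling((reach + r) / sp) + 1L)
    for (k in seq_along(structure$contents$ops)) {
      base <- molecule_image(structure, mol, k, c(0L, 0L, 0L))
      # centroid of the op image in fractional coordinates
      fc <- colMeans(base$fract)
      grid <- expand.grid(sx = -w[1]:w[1], sy = -w[2]:w[2], sz = -w[3]:w[3])
      cart_ctr <- frac_to_cart(structure$cell,
                               sweep(as.matrix(grid), 2, fc, "+"))
      dd <- sqrt(rowSums(sweep(cart_ctr, 2, center)^2))
      for (gi in which(dd <= reach + r)) {
        sh <- as.integer(grid[gi, ])
        img <- molecule_image(structure, mol, k, sh)
        out[[length(out) + 1L]] <- list(mol_id = mi, op = k, shift = sh,
                                        molecule = img)
      }
    }
  }
  # deduplicate coincident images (molecules on special positions)
  if (length(out) > 1) {
    keys <- vapply(out, function(rec) {
      xyz <- as.matrix(rec$molecule$atoms[, c("x", "y", "z")])
      paste(round(xyz[order(rec$molecule$atoms$label), ], 3), collapse = ",")
    }, character(1))
    out <- out[!duplicated(keys)]
  }
  out
}

prov_string <- function(op, shift) {
  sprintf("op%d[%d,%d,%d]", op, shift[1], shift[2], shift[3])
}

same_image <- function(rec, mol) {
  # is this image record the representative molecule itself?
  sqrt(sum((rec$molecule$centroid - mol$centroid)^2)) < 1e-6 &&
    molecule_label_key(rec$molecule) == molecule_label_key(mol)
}

# --- hydrogen bonds --------------------------------------------------------

#' Find hydrogen bonds in a crystal structure
#'
#' Enumerates every D-H...A triple over all symmetry and translation images
#' satisfying the geometric criteria, deduplicated by symmetry. Donors are
#' N/O atoms carrying a covalently bonded hydrogen; acceptors are N/O atoms
#' of any neighbouring image. Donor atoms of the given elements that carry no
#' modelled hydrogen (e.g. water with unrefined H) contribute to a separate
#' distance-only candidate list returned as the `"da_only"` attribute.
#'
#' @param structure A [crystal_structure()].
#' @param max_da Maximum donor...acceptor distance in Angstrom.
#' @param min_angle Minimum D-H...A angle in degrees.
#' @param donor_elements,acceptor_elements Element symbols eligible as donors
#'   and acceptors.
#' @return A tibble with one row per symmetry-distinct hydrogen bond: donor,
#'   hydrogen and acceptor labels, the acceptor image provenance, `d_da`
#'   (Angstrom) and `angle_dha` (degrees).
#' @export
find_hydrogen_bonds <- function(structure, max_da = 3.5, min_angle = 120,
                                donor_elements = c("N", "O"),
                                acceptor_elements = c("N", "O")) {
  rows <- list()
  cand <- list()
  for (mol in structure$molecules) {
    at <- mol$atoms
    bonded_h <- function(i) {
      b <- mol$bonds
      hits <- c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
      hits[at$element[hits] %in% c("H", "D")]
    }
    don_idx <- which(at$element %in% donor_elements)
    if (length(don_idx) == 0) next
    reach <- max_da + mol_radius(mol) + 0.1
    imgs <- enumerate_images(structure, mol$centroid, reach)
    for (di in don_idx) {
      D <- as.numeric(at[di, c("x", "y", "z")])
      hs <- bonded_h(di)
      for (rec in imgs) {
        img_at <- rec$molecule$atoms
        acc_idx <- which(img_at$element %in% acceptor_elements)
        for (ai in acc_idx) {
          A <- as.numeric(img_at[ai, c("x", "y", "z")])
          dda <- sqrt(sum((D - A)^2))
          if (dda > max_da || dda < 1e-3) next
          intra <- same_image(rec, mol)
          if (intra && img_at$label[ai] == at$label[di]) next
          if (intra) next  # intramolecular pairs excluded
          if (length(hs) == 0) {
            cand[[length(cand) + 1L]] <- tibble::tibble(
              donor = at$label[di], acceptor = img_at$label[ai],
              acceptor_prov = prov_string(rec$op, rec$shift), d_da = dda)
            next
          }
          for (hi in hs) {
            H <- as.numeric(at[hi, c("x", "y", "z")])
            v1 <- D - H
            v2 <- A - H
            ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang < min_angle) next
            rows[[length(rows) + 1L]] <- tibble::tibble(
              donor = at$label[di], hydrogen = at$label[hi],
              acceptor = img_at$label[ai],
              acceptor_prov = prov_string(rec$op, rec$shift),
              d_da = dda, angle_dha = ang)
          }
        }
      }
    }
  }
  hb <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(donor = character(0), hydrogen = character(0),
                   acceptor = character(0), acceptor_prov = character(0),
                   d_da = numeric(0), angle_dha = numeric(0))
  }
  # symmetry deduplication: one row per distinct (donor, acceptor, geometry)
  if (nrow(hb)) {
    key <- paste(hb$donor, hb$acceptor, round(hb$d_da, 3), round(hb$angle_dha, 1))
    hb <- hb[order(key), ]
    hb <- hb[!duplicated(paste(hb$donor, hb$acceptor, round(hb$d_da, 3),
                               round(hb$angle_dha, 1))), ]
    hb <- dplyr::arrange(hb, .data$donor, .data$acceptor, .data$d_da)
  }
  da <- if (length(cand)) {
    dd <- dplyr::bind_rows(cand)
    dd <- dd[!duplicated(paste(dd$donor, dd$acceptor, round(dd$d_da, 3))), ]
    dplyr::arrange(dd, .data$donor, .data$acceptor, .data$d_da)
  } else {
    tibble::tibble(donor = character(0), acceptor = character(0),
                   acceptor_prov = character(0), d_da = numeric(0))
  }
  attr(hb, "da_only") <- da
  hb
}

# --- close contacts --------------------------------------------------------

#' Find sub-van-der-Waals close contacts
#'
#' All intermolecular atom pairs whose distance falls below the sum of the
#' Bondi van der Waals radii plus `margin`, each reported once with canonical
#' ordering. Intramolecular pairs are excluded. For a cluster the pairs are
#' kernel-to-shell.
#'
#' @param x A [crystal_structure()] or a [build_cluster()] result.
#' @param margin Gap margin in Angstrom: contacts with
#'   `distance - vdw_sum < margin` are reported (0 = strictly sub-vdW).
#' @return Tibble with atom labels/elements, image provenance, `distance`,
#'   `vdw_sum` and `gap = distance - vdw_sum` (negative = sub-vdW).
#' @export
find_close_contacts <- function(x, margin = 0) {
  UseMethod("find_close_contacts")
}

contact_pairs <- function(at1, at2, prov, margin) {
  xyz1 <- as.matrix(at1[, c("x", "y", "z")])
  xyz2 <- as.matrix(at2[, c("x", "y", "z")])
  r1 <- vdw_radius(at1$element)
  r2 <- vdw_radius(at2$element)
  d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") - 2 * tcrossprod(xyz1, xyz2)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  cut <- outer(r1, r2, "+") + margin
  hit <- which(d < cut & d > 1e-6, arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  tibble::tibble(
    label_i = at1$label[hit[, 1]], element_i = at1$element[hit[, 1]],
    label_j = at2$label[hit[, 2]], element_j = at2$element[hit[, 2]],
    image_j = prov,
    distance = d[hit], vdw_sum = (outer(r1, r2, "+"))[hit],
    gap = d[hit] - (outer(r1, r2, "+"))[hit])
}

canonical_contacts <- function(ct) {
  if (is.null(ct) || nrow(ct) == 0) {
    return(tibble::tibble(label_i = character(0), element_i = character(0),
                          label_j = character(0), element_j = character(0),
                          image_j = character(0), distance = numeric(0),
                          vdw_sum = numeric(0), gap = numeric(0)))
  }
  swap <- ct$label_j < ct$label_i
  tmp_l <- ct$label_i[swap]; tmp_e <- ct$element_i[swap]
  ct$label_i[swap] <- ct$label_j[swap]; ct$element_i[swap] <- ct$element_j[swap]
  ct$label_j[swap] <- tmp_l; ct$element_j[swap] <- tmp_e
  key <- paste(ct$label_i, ct$label_j, round(ct$distance, 3))
  ct <- ct[order(key), ]
  ct <- ct[!duplicated(paste(ct$label_i, ct$label_j, round(ct$distance, 3))), ]
  dplyr::arrange(ct, .data$gap, .data$label_i, .data$label_j)
}

#' @export
find_close_contacts.crystal_structure <- function(x, margin = 0) {
  out <- list()
  max_vdw <- max(vdw_radius(unique(unlist(lapply(x$molecules,
                                                 function(m) m$atoms$element)))))
  for (mol in x$molecules) {
    reach <- 2 * max_vdw + margin + 2 * mol_radius(mol) + 0.1
    imgs <- enumerate_images(x, mol$centroid, reach)
    for (rec in imgs) {
      if (same_image(rec, mol)) next
      ct <- contact_pairs(mol$atoms, rec$molecule$atoms,
                          prov_string(rec$op, rec$shift), margin)
      if (!is.null(ct)) out[[length(out) + 1L]] <- ct
    }
  }
  canonical_contacts(if (length(out)) dplyr::bind_rows(out) else NULL)
}

#' @export
find_close_contacts.cluster <- function(x, margin = 0) {
  out <- list()
  for (rec in x$shell) {
    ct <- contact_pairs(x$kernel$atoms, rec$molecule$atoms,
                        prov_string(rec$op, rec$shift), margin)
    if (!is.null(ct)) out[[length(out) + 1L]] <- ct
  }
  canonical_contacts(if (length(out)) dplyr::bind_rows(out) else NULL)
}
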