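# Coordination-sphere cluster around a kernel molecule: the comparison unit
# of the packing-similarity engine.

#' Build the coordination-sphere cluster of a kernel molecule
#'
#' The shell holds every symmetry/translation image of every symmetry-distinct
#' molecule having at least one atom within (van der Waals sum + margin) of a
#' kernel atom, ordered deterministically by (centroid distance, operator
#' index, translation). The translation search window is derived from the
#' contact reach, so enlarging it cannot add members.
#'
#' @param structure A [crystal_structure()].
#' @param kernel Kernel molecule; defaults to the largest (host) molecule.
#' @param margin Contact margin in Angstrom added to the vdW sum (default 1.5).
#' @param include_waters Keep water/solvent molecules in the shell.
#' @return An object of class `cluster`: `kernel`, `shell` (list of records
#'   with `molecule`, `op`, `shift`, `mol_id`, `dist`), `margin`, `structure`.
#' @export
build_cluster <- function(structure, kernel = NULL, margin = 1.5,
                          include_waters = TRUE) {
  kernel <- kernel %||% host_molecule(structure)
  keys <- vapply(structure$molecules, molecule_label_key, character(1))
  if (!molecule_label_key(kernel) %in% keys) {
    stop("kernel molecule is not one of the structure's representatives",
         call. = FALSE)
  }
  elements <- unique(unlist(lapply(structure$molecules,
                                   function(m) m$atoms$element)))
  max_vdw_sum <- 2 * max(vdw_radius(elements))
  r_shell <- max(vapply(structure$molecules, mol_radius, numeric(1)))
  reach <- mol_radius(kernel) + r_shell + max_vdw_sum + margin + 0.1
  imgs <- enumerate_images(structure, kernel$centroid, reach)
  kxyz <- as.matrix(kernel$atoms[, c("x", "y", "z")])
  krad <- vdw_radius(kernel$atoms$element)
  shell <- list()
  for (rec in imgs) {
    if (same_image(rec, kernel)) next
    if (!include_waters && is_water(rec$molecule)) next
    at <- rec$molecule$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")])
    d2 <- outer(rowSums(kxyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(kxyz, xyz)
    d2[d2 < 0] <- 0
    cut <- outer(krad, vdw_radius(at$element), "+") + margin
    if (any(sqrt(d2) <= cut)) {
      rec$dist <- sqrt(sum((rec$molecule$centroid - kernel$centroid)^2))
      shell[[length(shell) + 1L]] <- rec
    }
  }
  ord <- order(vapply(shell, function(s) round(s$dist, 6), numeric(1)),
               vapply(shell, function(s) s$op, numeric(1)),
               vapply(shell, function(s) paste(s$shift, collapse = ","),
                      character(1)))
  structure(list(kernel = kernel, shell = shell[ord], margin = margin,
                 structure = structure),
            class = "cluster")
}

is_water <- function(mol) {
  el <- sort(mol$atoms$element)
  identical(el, "O") || identical(el, c("H", "H", "O")) || identical(el, c("H", "O"))
}

#' @export
print.cluster <- function(x, ...) {
  cat(sprintf("<cluster> kernel %d atoms, shell of %d molecules (margin %.2f A)\n",
              nrow(x$kernel$atoms), length(x$shell), x$margin))
  invisible(x)
}

#' Cluster fingerprint
#'
#' Sorted multiset of shell centroid distances with a provenance class
#' (proper translation / proper rotation / improper) -- a cheap pre-filter:
#' clusters whose fingerprints disagree beyond the distance tolerance on any
#' prefix cannot match in full.
#'
#' @param cluster A [build_cluster()] result.
#' @return Tibble with columns `dist` (Angstrom, ascending) and `prov_class`.
#' @export
cluster_fingerprint <- function(cluster) {
  ops <- cluster$structure$contents$ops
  cls <- vapply(cluster$shell, function(rec) {
    op <- ops[[rec$op]]
    if (round(det(op$rot)) < 0) "improper"
    else if (symop_is_translation(op)) "translation"
    else "rotation"
  }, character(1))
  d <- vapply(cluster$shell, function(rec) rec$dist, numeric(1))
  tibble::tibble(dist = d, prov_class = cls)[order(d), ]
}
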