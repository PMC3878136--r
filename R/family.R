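# Family-level comparison: merge pairwise matched motifs into supramolecular
# constructs (SCs) with dimensionality, base vectors, membership and
# sub-construct dependencies, named A01/A11/.../B11 style.

# simplified descriptor rows (lists) from the A side of a match
match_motif_descriptors <- function(match) {
  da <- attr(match, "desc_a")
  idx <- match(match$a, vapply(da, function(p) p$shell_index, integer(1)))
  da[idx]
}

# greedy one-to-one embedding of descriptor set `small` into `big`
desc_embeds <- function(small, big, tol_d, tol_ang) {
  if (length(small) > length(big)) return(FALSE)
  used <- logical(length(big))
  for (s in small) {
    devs <- vapply(seq_along(big), function(j) {
      if (used[j]) return(Inf)
      desc_deviation(s, big[[j]], tol_d, tol_ang)
    }, numeric(1))
    j <- which.min(devs)
    if (!is.finite(devs[j])) return(FALSE)
    used[j] <- TRUE
  }
  TRUE
}

desc_congruent <- function(a, b, tol_d, tol_ang) {
  length(a) == length(b) && desc_embeds(a, b, tol_d, tol_ang) &&
    desc_embeds(b, a, tol_d, tol_ang)
}

sc_description <- function(dim, has_improper) {
  motif <- if (has_improper) "dimer" else "molecule"
  switch(as.character(dim),
         "0" = paste0("discrete ", motif, " assembly"),
         "1" = paste0("1D ", motif, " stack/tape"),
         "2" = paste0("2D ", motif, " layer"),
         "3" = "isostructural set")
}

#' Detect supramolecular constructs across a family of structures
#'
#' Runs all pairwise cluster comparisons, then merges matched motifs that are
#' descriptor-congruent (pairwise, against the first-seen exemplar) into
#' supramolecular constructs. Each SC records its dimensionality, base-vector
#' magnitudes (range across exhibiting pairs), member structures (every
#' structure appearing in a pairwise match that contains the SC's descriptor
#' set) and sub-construct dependencies (descriptor containment with strictly
#' lower dimensionality). SC ids follow the family-letter + dimensionality +
#' ordinal convention (A01, A11, ..., B11): lineages connected by containment
#' share a letter.
#'
#' @param structures List of [crystal_structure()] (or [cell_contents()])
#'   objects; at least 2 for a non-empty result.
#' @param corr `"auto"` or an explicit label vector used for every pair.
#' @param tol_d,tol_ang Matching tolerances, see [match_clusters()].
#' @param margin Cluster contact margin in Angstrom.
#' @param include_waters Keep solvent in cluster shells.
#' @return A tibble of class `sc_set` with one row per SC: `sc_id`,
#'   `dimensionality`, `description`, `n_members`, `members` (list),
#'   `base_magnitudes` (list), `base_labels` (list), `depends_on` (list).
#'   Pairwise comparison details are attached as attribute `"pairs"`.
#' @export
compare_family <- function(structures, corr = "auto", tol_d = 0.5,
                           tol_ang = 12, margin = 1.5,
                           include_waters = TRUE) {
  structures <- lapply(structures, function(s) {
    if (inherits(s, "cell_contents")) crystal_structure(s) else s
  })
  ids <- vapply(structures, function(s) s$contents$structure_id, character(1))
  if (anyDuplicated(ids)) stop("structure ids must be unique", call. = FALSE)
  empty <- tibble::tibble(sc_id = character(0), dimensionality = integer(0),
                          description = character(0), n_members = integer(0),
                          members = list(), base_magnitudes = list(),
                          base_labels = list(), depends_on = list())
  class(empty) <- c("sc_set", class(empty))
  if (length(structures) < 2) return(empty)

  clusters <- lapply(structures, build_cluster, margin = margin,
                     include_waters = include_waters)
  protos <- list()
  pair_rows <- list()
  motifs <- list()
  for (i in seq_along(structures)) {
    for (j in seq_along(structures)) {
      if (i >= j) next
      cr <- tryCatch(
        if (inherits(corr, "correspondence")) corr else
          make_correspondence(structures[[i]], structures[[j]], corr),
        error = function(e) NULL)
      if (is.null(cr)) next
      m <- match_clusters(clusters[[i]], clusters[[j]], cr,
                          tol_d = tol_d, tol_ang = tol_ang)
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        id_a = ids[i], id_b = ids[j], n_matched = nrow(m),
        dimensionality = if (nrow(m)) derive_dimensionality(m)$dimensionality
                         else NA_integer_)
      if (nrow(m) == 0) next
      dm <- derive_dimensionality(m)
      motif <- list(desc = match_motif_descriptors(m), dim = dm$dimensionality,
                    mags = sort(dm$magnitudes),
                    mags_b = sort(dm$magnitudes_b),
                    members = c(ids[i], ids[j]))
      motifs[[length(motifs) + 1L]] <- motif
      hit <- NULL
      for (p in seq_along(protos)) {
        if (protos[[p]]$dim == motif$dim &&
            desc_congruent(protos[[p]]$desc, motif$desc, tol_d, tol_ang)) {
          hit <- p
          break
        }
      }
      if (is.null(hit)) {
        protos[[length(protos) + 1L]] <- list(
          desc = motif$desc, dim = motif$dim, members = motif$members,
          mags = list(motif$mags, motif$mags_b))
      } else {
        protos[[hit]]$members <- union(protos[[hit]]$members, motif$members)
        protos[[hit]]$mags <- c(protos[[hit]]$mags,
                                list(motif$mags, motif$mags_b))
      }
    }
  }
  if (length(protos) == 0) {
    attr(empty, "pairs") <- dplyr::bind_rows(pair_rows)
    return(empty)
  }
  # membership extension: a structure exhibits an SC when any of its pairwise
  # motifs contains the SC's descriptor set
  for (p in seq_along(protos)) {
    for (mo in motifs) {
      if (length(protos[[p]]$desc) <= length(mo$desc) &&
          desc_embeds(protos[[p]]$desc, mo$desc, tol_d, tol_ang)) {
        protos[[p]]$members <- union(protos[[p]]$members, mo$members)
      }
    }
  }
  # containment relation among prototypes
  np <- length(protos)
  contains <- matrix(FALSE, np, np)  # contains[x, y]: proto x contains proto y
  for (x in seq_len(np)) {
    for (y in seq_len(np)) {
      if (x == y) next
      if (length(protos[[y]]$desc) < length(protos[[x]]$desc) &&
          protos[[y]]$dim < protos[[x]]$dim &&
          desc_embeds(protos[[y]]$desc, protos[[x]]$desc, tol_d, tol_ang)) {
        contains[x, y] <- TRUE
      }
    }
  }
  # families: connected components of the containment relation, lettered in
  # prototype-creation order
  fam <- rep(NA_integer_, np)
  next_fam <- 0L
  for (p in seq_len(np)) {
    if (!is.na(fam[p])) next
    next_fam <- next_fam + 1L
    queue <- p
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(fam[u])) next
      fam[u] <- next_fam
      nb <- which(contains[u, ] | contains[, u])
      queue <- c(queue, nb[is.na(fam[nb])])
    }
  }
  # ids: letter by family, digit1 = dimensionality, digit2 = ordinal in
  # creation order within (family, dimensionality)
  sc_id <- character(np)
  for (p in seq_len(np)) {
    ordinal <- sum(fam[seq_len(p)] == fam[p] &
                     vapply(protos[seq_len(p)], function(q) q$dim,
                            numeric(1)) == protos[[p]]$dim)
    sc_id[p] <- paste0(LETTERS[fam[p]], protos[[p]]$dim, ordinal)
  }
  # base-vector labels: t1, t2, ... assigned in SC order; a vector magnitude
  # already labelled in a contained SC reuses its label
  t_labels <- list()
  next_t <- 0L
  base_labels <- vector("list", np)
  for (p in seq_len(np)) {
    mags <- sort(protos[[p]]$mags[[1]])
    labs <- character(length(mags))
    for (k in seq_along(mags)) {
      reuse <- NULL
      for (q in seq_len(np)) {
        if (q < p && contains[p, q]) {
          prev <- base_labels[[q]]
          pm <- sort(protos[[q]]$mags[[1]])
          hitk <- which(abs(pm - mags[k]) <= tol_d)
          if (length(hitk)) reuse <- prev[hitk[1]]
        }
      }
      if (is.null(reuse)) {
        next_t <- next_t + 1L
        labs[k] <- paste0("t", next_t)
      } else {
        labs[k] <- reuse
      }
    }
    base_labels[[p]] <- labs
  }
  depends_on <- lapply(seq_len(np), function(x) sort(sc_id[contains[x, ]]))
  has_imp <- vapply(protos, function(p) {
    any(vapply(p$desc, function(d) d$improper, logical(1)))
  }, logical(1))
  out <- tibble::tibble(
    sc_id = sc_id,
    dimensionality = vapply(protos, function(p) as.integer(p$dim), integer(1)),
    description = vapply(seq_len(np), function(p) {
      sc_description(protos[[p]]$dim, has_imp[p])
    }, character(1)),
    n_members = vapply(protos, function(p) length(p$members), integer(1)),
    members = lapply(protos, function(p) sort(p$members)),
    base_magnitudes = lapply(protos, function(p) {
      mags <- do.call(rbind, p$mags)
      if (is.null(mags) || length(mags) == 0) numeric(0) else
        apply(mags, 2, mean)
    }),
    base_labels = base_labels,
    depends_on = depends_on)
  out <- out[order(out$sc_id), ]
  attr(out, "pairs") <- dplyr::bind_rows(pair_rows)
  attr(out, "base_range") <- lapply(protos, function(p) {
    mags <- do.call(rbind, p$mags)
    if (is.null(mags) || length(mags) == 0) numeric(0) else
      apply(mags, 2, range)
  })
  class(out) <- c("sc_set", class(out))
  out
}

#' @export
print.sc_set <- function(x, ...) {
  cat("<sc_set> ", nrow(x), " supramolecular construct(s)\n", sep = "")
  if (nrow(x)) {
    df <- data.frame(
      SC = x$sc_id, D = x$dimensionality, n = x$n_members,
      base = vapply(x$base_magnitudes, function(m) {
        if (length(m) == 0) "" else paste(sprintf("%.2f", sort(m)),
                                          collapse = ", ")
      }, character(1)),
      depends = vapply(x$depends_on, paste, character(1), collapse = ","))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize an SC set as a flat table
#'
#' Flattens the list columns of [compare_family()] output into a plain tibble
#' suitable for CSV export (one row per SC, comma-separated members and base
#' vectors).
#'
#' @param scs An `sc_set`.
#' @return A tibble with character columns only.
#' @export
sc_table <- function(scs) {
  tibble::tibble(
    sc_id = scs$sc_id,
    dimensionality = scs$dimensionality,
    description = scs$description,
    n_members = scs$n_members,
    members = vapply(scs$members, paste, character(1), collapse = ";"),
    base_vectors = vapply(seq_len(nrow(scs)), function(i) {
      m <- scs$base_magnitudes[[i]]
      if (length(m) == 0) return("")
      paste(sprintf("%s (%.3f)", scs$base_labels[[i]], sort(m)),
            collapse = "; ")
    }, character(1)),
    dependencies = vapply(seq_len(nrow(scs)), function(i) {
      dep <- scs$depends_on[[i]]
      if (length(dep) == 0) "primary SC" else
        paste(paste0(scs$sc_id[i], "->", dep), collapse = "; ")
    }, character(1)))
}
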