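# Command-level entry points tying the stages together: per-structure audit,
# family comparison with SC table + relationship graph, synthetic generation.
# A thin Rscript front end (exec/packmotif) dispatches to these.

#' Audit crystal structures from CIF files
#'
#' For each input: cell metrics (volume, inferred Z, calculated density when
#' a formula weight is available), hydrogen bonds, sub-vdW close contacts and
#' the molecule census. When the CIF states a cell volume, the computed value
#' is cross-checked and a discrepancy above 0.5 percent is flagged.
#'
#' @param paths Character vector of CIF file paths.
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes `<id>_audit.json` per structure.
#' @return A tibble with one row per structure (`volume`, `density`, `z`,
#'   `n_molecules`, `n_hbonds`, `n_contacts`, `volume_flag`); the detailed
#'   per-structure reports are attached as attribute `"reports"`.
#' @export
audit_structures <- function(paths, config = run_config(), out_dir = NULL) {
  rows <- list()
  reports <- list()
  for (path in paths) {
    contents <- read_cif(path)
    st <- crystal_structure(contents,
                            bond_tolerance = config$bond_tolerance)
    vol <- cell_volume(contents$cell)
    vflag <- FALSE
    if (!is.null(contents$stated_volume) && is.finite(contents$stated_volume)) {
      vflag <- abs(vol - contents$stated_volume) / contents$stated_volume > 0.005
      if (vflag) {
        warning("computed volume deviates >0.5% from the CIF value in ",
                path, call. = FALSE)
      }
    }
    z <- tryCatch(
      if (!is.null(contents$z)) contents$z else if (!is.null(contents$fw)) {
        as.integer(infer_z(contents$cell, contents$fw,
                           n_ops = length(contents$ops)))
      } else NA_integer_,
      error = function(e) NA_integer_)
    dens <- if (!is.na(z) && !is.null(contents$fw)) {
      calc_density(contents$cell, contents$fw, z)
    } else NA_real_
    hb <- find_hydrogen_bonds(st, max_da = config$max_da,
                              min_angle = config$min_angle)
    ct <- find_close_contacts(st, margin = config$contact_margin)
    id <- contents$structure_id
    rows[[length(rows) + 1L]] <- tibble::tibble(
      structure_id = id, volume = vol, z = z, density = dens,
      n_molecules = length(st$molecules), n_hbonds = nrow(hb),
      n_contacts = nrow(ct), volume_flag = vflag)
    rep <- list(structure_id = id, cell = unclass(contents$cell),
                volume = vol, z = z, density = dens,
                hydrogen_bonds = hb, da_candidates = attr(hb, "da_only"),
                close_contacts = ct)
    reports[[id]] <- rep
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      jsonlite::write_json(rep, file.path(out_dir, paste0(id, "_audit.json")),
                           dataframe = "rows", auto_unbox = TRUE, digits = 6)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reports") <- reports
  out
}

#' Family comparison report
#'
#' Compares all input structures pairwise, detects supramolecular constructs
#' and builds the relationship graph. With `out_dir` set, writes the SC table
#' (CSV), the machine-readable SC report (JSON) and the graph (DOT + JSON);
#' outputs are deterministic given inputs and configuration.
#'
#' @param paths CIF file paths (at least 2) or a list of
#'   [crystal_structure()] objects.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List of class `family_report`: `scs` (the `sc_set`), `graph`
#'   (the [build_graph()] result), `table` (flat SC tibble).
#' @export
family_report <- function(paths, config = run_config(), out_dir = NULL) {
  structures <- if (is.character(paths)) {
    if (length(paths) < 2) stop("family comparison needs >= 2 inputs",
                                call. = FALSE)
    lapply(paths, function(p) {
      crystal_structure(read_cif(p), bond_tolerance = config$bond_tolerance)
    })
  } else {
    if (length(paths) < 2) stop("family comparison needs >= 2 inputs",
                                call. = FALSE)
    paths
  }
  scs <- compare_family(structures, tol_d = config$tol_d,
                        tol_ang = config$tol_ang, margin = config$margin,
                        include_waters = !config$host_only)
  ids <- vapply(structures, function(s) s$contents$structure_id, character(1))
  graph <- build_graph(scs, structures = ids)
  tab <- sc_table(scs)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "sc_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(scs = tab, pairs = attr(scs, "pairs")),
      file.path(out_dir, "sc_report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = 6)
    writeLines(to_dot(graph), file.path(out_dir, "relationships.dot"))
    writeLines(graph_to_json(graph), file.path(out_dir, "relationships.json"))
  }
  structure(list(scs = scs, graph = graph, table = tab),
            class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  print(x$scs)
  invisible(x)
}

#' Generate a synthetic crystal and its ground truth
#'
#' Builds the motif, writes the CIF (with the generating spec recorded as a
#' comment) and a JSON ground-truth sidecar.
#'
#' @param spec A [motif_spec()].
#' @param out_dir Output directory.
#' @param structure_id Optional id (defaults to a kind/seed-derived name).
#' @return Invisible list with the written `cif` and `truth` paths.
#' @export
generate_crystal <- function(spec, out_dir = ".", structure_id = NULL) {
  syn <- build_crystal(spec, structure_id = structure_id)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  id <- syn$contents$structure_id
  cif_path <- file.path(out_dir, paste0(id, ".cif"))
  truth_path <- file.path(out_dir, paste0(id, "_truth.json"))
  write_cif(syn$contents, cif_path,
            comment = sprintf("synthetic motif %s seed %d sigma %g",
                              spec$kind, spec$seed, spec$noise))
  jsonlite::write_json(syn$truth, truth_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = 8)
  invisible(list(cif = cif_path, truth = truth_path))
}
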