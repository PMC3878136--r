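# Run configuration: tolerances and flags shared by the command-level
# functions, with a flat diffable key=value file format.

#' Pipeline run configuration
#'
#' @param tol_d Distance matching tolerance in Angstrom.
#' @param tol_ang Angular matching tolerance in degrees.
#' @param max_da Hydrogen-bond donor...acceptor cutoff in Angstrom.
#' @param min_angle Hydrogen-bond minimum D-H...A angle in degrees.
#' @param bond_tolerance Bond-perception tolerance in Angstrom.
#' @param margin Cluster contact margin in Angstrom.
#' @param contact_margin Close-contact report margin in Angstrom.
#' @param host_only Exclude solvent molecules from cluster shells.
#' @param seed Integer seed for generation commands.
#' @return List of class `run_config`.
#' @export
run_config <- function(tol_d = 0.5, tol_ang = 12, max_da = 3.5,
                       min_angle = 120, bond_tolerance = 0.40, margin = 1.5,
                       contact_margin = 0, host_only = FALSE, seed = 1L) {
  num <- c(tol_d = tol_d, tol_ang = tol_ang, max_da = max_da,
           min_angle = min_angle, bond_tolerance = bond_tolerance,
           margin = margin)
  if (any(num <= 0)) stop("all tolerances must be positive", call. = FALSE)
  structure(list(tol_d = tol_d, tol_ang = tol_ang, max_da = max_da,
                 min_angle = min_angle, bond_tolerance = bond_tolerance,
                 margin = margin, contact_margin = contact_margin,
                 host_only = isTRUE(host_only), seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration file
#'
#' Flat `key = value` text with one canonical serialization; round-trips
#' losslessly through [read_run_config()].
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return The lines written, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- c("# packmotif run configuration",
             vapply(names(config), function(k) {
               v <- config[[k]]
               sprintf("%s = %s", k,
                       if (is.logical(v)) tolower(as.character(v)) else
                         format(v, scientific = FALSE))
             }, character(1)))
  writeLines(lines, path)
  invisible(lines)
}

#' Read a run configuration file
#'
#' @param path Path to a file written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- list()
  for (p in kv) {
    k <- trimws(p[1])
    v <- trimws(paste(p[-1], collapse = "="))
    vals[[k]] <- if (v %in% c("true", "false")) v == "true" else as.numeric(v)
  }
  do.call(run_config, vals)
}
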