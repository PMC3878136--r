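# Minimal CIF 1.1 reader/writer for small-molecule structures: cell
# parameters, symmetry operators as xyz strings (old or new tag naming), and
# the atom-site loop with fractional coordinates and occupancies.

#' Construct cell contents
#'
#' The root input object of the pipeline: unit cell, symmetry operators and
#' asymmetric-unit atom sites, with optional formula weight and Z.
#'
#' @param structure_id Text identifier for the structure.
#' @param cell A [unit_cell()].
#' @param ops List of [parse_symop()] operators; the identity is added if
#'   absent.
#' @param sites A data frame with columns `label`, `element`, `x`, `y`, `z`
#'   (fractional coordinates) and optionally `occupancy` (defaults to 1).
#'   Fractional coordinates are wrapped into `[0, 1)`.
#' @param fw Optional formula weight (g/mol per formula unit).
#' @param z Optional number of formula units per cell.
#' @return An object of class `cell_contents`.
#' @export
cell_contents <- function(structure_id, cell, ops, sites, fw = NULL, z = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  sites <- tibble::as_tibble(sites)
  req <- c("label", "element", "x", "y", "z")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"occupancy" %in% names(sites)) sites$occupancy <- 1
  sites$occupancy[is.na(sites$occupancy)] <- 1
  if (any(sites$occupancy <= 0 | sites$occupancy > 1)) {
    stop("occupancies must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(sites$label)) {
    stop("atom-site labels must be unique within a structure", call. = FALSE)
  }
  bad <- !is_known_element(sites$element)
  if (any(bad)) {
    stop("unrecognized element symbol(s): ",
         paste(unique(sites$element[bad]), collapse = ", "), call. = FALSE)
  }
  sites$x <- sites$x %% 1
  sites$y <- sites$y %% 1
  sites$z <- sites$z %% 1
  if (!any(vapply(ops, symop_is_identity, logical(1)))) {
    ops <- c(list(parse_symop("x, y, z")), ops)
  }
  structure(list(structure_id = structure_id, cell = cell, ops = ops,
                 sites = sites, fw = fw, z = z),
            class = "cell_contents")
}

#' @export
print.cell_contents <- function(x, ...) {
  cat(sprintf("<cell_contents> %s: %d sites, %d operators\n",
              x$structure_id, nrow(x$sites), length(x$ops)))
  print(x$cell)
  invisible(x)
}

# Tokenize one CIF line into values, honouring single/double quotes.
cif_tokens <- function(line) {
  out <- character(0)
  s <- trimws(line)
  while (nzchar(s)) {
    if (startsWith(s, "'") || startsWith(s, "\"")) {
      q <- substr(s, 1, 1)
      rest <- substring(s, 2)
      pos <- regexpr(q, rest, fixed = TRUE)
      if (pos < 0) stop("unterminated quote in CIF line: ", line, call. = FALSE)
      out <- c(out, substr(rest, 1, pos - 1))
      s <- trimws(substring(rest, pos + 1))
    } else {
      pos <- regexpr("[[:space:]]", s)
      if (pos < 0) {
        out <- c(out, s)
        s <- ""
      } else {
        out <- c(out, substr(s, 1, pos - 1))
        s <- trimws(substring(s, pos))
      }
    }
  }
  out
}

# "12.345(6)" -> 12.345 ; "." / "?" -> NA
cif_number <- function(x) {
  x <- sub("\\(.*\\)$", "", x)
  suppressWarnings(ifelse(x %in% c(".", "?"), NA_real_, as.numeric(x)))
}

.cif_symop_tags <- c("_symmetry_equiv_pos_as_xyz",
                     "_space_group_symop_operation_xyz")

#' Parse a CIF document
#'
#' Reads the minimal small-molecule CIF dialect: cell lengths and angles,
#' symmetry operators given as xyz strings under either the older
#' `_symmetry_equiv_pos_as_xyz` or the newer
#' `_space_group_symop_operation_xyz` tag, and the atom-site loop (label,
#' optional type symbol, fractional x/y/z, optional occupancy). When the type
#' symbol column is absent the element is inferred from the label. Fractional
#' coordinates are wrapped into `[0, 1)`; missing occupancies default to 1.
#'
#' @param text CIF document as a single string or character vector of lines.
#' @param structure_id Optional identifier; defaults to the `data_` block name.
#' @return A [cell_contents()] object. Any `_cell_volume` and
#'   `_chemical_formula_weight`/`_chemical_formula_sum` values present are
#'   attached as fields `stated_volume` and `fw`.
#' @export
parse_cif <- function(text, structure_id = NULL) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]

  scalars <- list()
  loops <- list()
  block_name <- NULL
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (grepl("^data_", ln)) {
      if (is.null(block_name)) block_name <- sub("^data_", "", ln)
      i <- i + 1L
    } else if (identical(tolower(ln), "loop_")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, tolower(trimws(lines[i])))
        i <- i + 1L
      }
      rows <- list()
      vals <- character(0)
      while (i <= n) {
        ln2 <- trimws(lines[i])
        if (grepl("^(_|loop_|data_)", ln2, ignore.case = TRUE)) break
        vals <- c(vals, cif_tokens(ln2))
        i <- i + 1L
      }
      if (length(tags) > 0 && length(vals) %% length(tags) == 0 && length(vals) > 0) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        colnames(m) <- tags
        loops[[length(loops) + 1L]] <- m
      } else if (length(tags) > 0 && length(vals) > 0) {
        stop("CIF loop with tags ", paste(tags, collapse = ", "),
             " has a ragged value list", call. = FALSE)
      }
    } else if (grepl("^_", ln)) {
      toks <- cif_tokens(ln)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        scalars[[tag]] <- paste(toks[-1], collapse = " ")
        i <- i + 1L
      } else if (i + 1L <= n && grepl("^;", trimws(lines[i + 1L]))) {
        # multi-line semicolon text field: skip
        i <- i + 2L
        while (i <= n && !grepl("^;", trimws(lines[i]))) i <- i + 1L
        i <- i + 1L
      } else if (i + 1L <= n) {
        scalars[[tag]] <- paste(cif_tokens(trimws(lines[i + 1L])), collapse = " ")
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  for (tag in need) {
    if (is.null(scalars[[tag]])) {
      stop("CIF parse error: missing mandatory tag ", tag, call. = FALSE)
    }
  }
  cellp <- vapply(need, function(tag) cif_number(scalars[[tag]]), numeric(1))
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])

  # symmetry operators
  ops <- NULL
  for (lp in loops) {
    hit <- intersect(colnames(lp), .cif_symop_tags)
    if (length(hit) > 0) {
      ops <- lapply(lp[, hit[1]], parse_symop)
      break
    }
  }
  if (is.null(ops)) {
    for (tag in .cif_symop_tags) {
      if (!is.null(scalars[[tag]])) {
        ops <- list(parse_symop(scalars[[tag]]))
        break
      }
    }
  }
  if (is.null(ops)) {
    stop("CIF parse error: missing mandatory tag _symmetry_equiv_pos_as_xyz ",
         "(or _space_group_symop_operation_xyz)", call. = FALSE)
  }

  # atom sites
  site_lp <- NULL
  for (lp in loops) {
    if ("_atom_site_label" %in% colnames(lp) &&
        all(c("_atom_site_fract_x", "_atom_site_fract_y",
              "_atom_site_fract_z") %in% colnames(lp))) {
      site_lp <- lp
      break
    }
  }
  if (is.null(site_lp)) {
    stop("CIF parse error: missing mandatory tag _atom_site_label ",
         "(atom-site loop with fractional coordinates)", call. = FALSE)
  }
  label <- as.character(site_lp[, "_atom_site_label"])
  element <- if ("_atom_site_type_symbol" %in% colnames(site_lp)) {
    el <- as.character(site_lp[, "_atom_site_type_symbol"])
    # strip oxidation-state decorations like "O2-"
    sub("[0-9+-]+$", "", el)
  } else {
    element_from_label(label)
  }
  occ <- if ("_atom_site_occupancy" %in% colnames(site_lp)) {
    o <- cif_number(site_lp[, "_atom_site_occupancy"])
    ifelse(is.na(o), 1, o)
  } else {
    rep(1, length(label))
  }
  sites <- tibble::tibble(
    label = label,
    element = element,
    x = cif_number(site_lp[, "_atom_site_fract_x"]),
    y = cif_number(site_lp[, "_atom_site_fract_y"]),
    z = cif_number(site_lp[, "_atom_site_fract_z"]),
    occupancy = occ
  )
  if (anyNA(sites[c("x", "y", "z")])) {
    stop("CIF parse error: non-numeric fractional coordinate in atom-site loop",
         call. = FALSE)
  }

  fw <- if (!is.null(scalars[["_chemical_formula_weight"]])) {
    cif_number(scalars[["_chemical_formula_weight"]])
  } else if (!is.null(scalars[["_chemical_formula_sum"]])) {
    formula_weight(gsub(" ", "", scalars[["_chemical_formula_sum"]]))
  } else {
    NULL
  }
  z <- if (!is.null(scalars[["_cell_formula_units_z"]])) {
    as.integer(cif_number(scalars[["_cell_formula_units_z"]]))
  } else {
    NULL
  }

  id <- structure_id %||% block_name %||% "structure"
  out <- cell_contents(id, cell, ops, sites, fw = fw, z = z)
  if (!is.null(scalars[["_cell_volume"]])) {
    out$stated_volume <- cif_number(scalars[["_cell_volume"]])
  }
  out
}

#' Read a CIF file
#'
#' @param path Path to a CIF file.
#' @param structure_id Optional identifier; defaults to the file's block name.
#' @return A [cell_contents()] object.
#' @export
read_cif <- function(path, structure_id = NULL) {
  if (!file.exists(path)) stop("cannot read CIF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0L || all(!nzchar(trimws(lines)))) {
    stop("CIF parse error: file '", path, "' is empty", call. = FALSE)
  }
  parse_cif(lines, structure_id = structure_id)
}

#' Write cell contents as CIF text
#'
#' Serializes the same minimal dialect [parse_cif()] reads; a
#' `write_cif(parse_cif(x))` round trip is idempotent on the supported tags.
#'
#' @param contents A [cell_contents()] object.
#' @param path Optional file path; when given the text is also written there.
#' @param comment Optional comment line(s) placed at the top of the file.
#' @return The CIF document as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_cif <- function(contents, path = NULL, comment = NULL) {
  stopifnot(inherits(contents, "cell_contents"))
  num <- function(x, d = 6) formatC(x, format = "f", digits = d)
  lines <- c(
    if (!is.null(comment)) paste0("# ", comment),
    paste0("data_", contents$structure_id),
    paste("_cell_length_a", num(contents$cell$a, 5)),
    paste("_cell_length_b", num(contents$cell$b, 5)),
    paste("_cell_length_c", num(contents$cell$c, 5)),
    paste("_cell_angle_alpha", num(contents$cell$alpha, 4)),
    paste("_cell_angle_beta", num(contents$cell$beta, 4)),
    paste("_cell_angle_gamma", num(contents$cell$gamma, 4)),
    paste("_cell_volume", num(cell_volume(contents$cell), 3))
  )
  if (!is.null(contents$fw)) {
    lines <- c(lines, paste("_chemical_formula_weight", num(contents$fw, 2)))
  }
  if (!is.null(contents$z)) {
    lines <- c(lines, paste("_cell_formula_units_Z", contents$z))
  }
  lines <- c(lines, "loop_", "_space_group_symop_operation_xyz",
             vapply(contents$ops, function(op) paste0("'", op$xyz, "'"),
                    character(1)))
  lines <- c(lines, "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "_atom_site_occupancy")
  s <- contents$sites
  wrap6 <- function(x) num(round(x, 6) %% 1)
  lines <- c(lines, sprintf("%s %s %s %s %s %s",
                            s$label, s$element, wrap6(s$x), wrap6(s$y),
                            wrap6(s$z), num(s$occupancy, 4)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
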