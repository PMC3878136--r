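# Space-group symmetry operators given as xyz strings ("x, y, z",
# "-x+1/2, y+1/2, -z", ...): parsing, serialization, composition.

#' Parse a symmetry operator xyz string
#'
#' Converts an operator such as `"-x+1/2, y+1/2, -z"` into a 3x3 integer
#' rotation matrix acting on fractional coordinates plus a translation vector
#' with components reduced into `[0, 1)`.
#'
#' @param xyz Operator string: three comma-separated components in x, y, z
#'   with optional rational or decimal translations.
#' @return A list with elements `rot` (3x3 integer matrix), `trans` (length-3
#'   numeric) and `xyz` (canonical string form); class `symop`.
#' @examples
#' parse_symop("-x+1/2, y+1/2, -z")
#' @export
parse_symop <- function(xyz) {
  raw <- xyz
  s <- tolower(gsub("[[:space:]]", "", xyz))
  comps <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(comps) != 3L) {
    stop("malformed symmetry operator string: '", raw, "'", call. = FALSE)
  }
  rot <- matrix(0L, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    comp <- comps[i]
    toks <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    if (length(toks) == 0L || paste(toks, collapse = "") != comp) {
      stop("malformed symmetry operator component: '", comp,
           "' in '", raw, "'", call. = FALSE)
    }
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        j <- match(body, c("x", "y", "z"))
        rot[i, j] <- rot[i, j] + as.integer(sign)
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        trans[i] <- trans[i] + sign * nd[1] / nd[2]
      } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
        trans[i] <- trans[i] + sign * as.numeric(body)
      } else if (grepl("^[0-9]+/[0-9]+[xyz]$", body) || grepl("^[0-9.]+[xyz]$", body)) {
        # coefficients other than +/-1 do not occur in space-group operators
        stop("unsupported coefficient in operator component '", comp,
             "' of '", raw, "'", call. = FALSE)
      } else {
        stop("malformed token '", tok, "' in operator '", raw, "'", call. = FALSE)
      }
    }
  }
  d <- round(det(rot))
  if (!d %in% c(-1, 1)) {
    stop("operator rotation determinant is ", d, " (must be +/-1): '",
         raw, "'", call. = FALSE)
  }
  trans <- trans %% 1
  op <- list(rot = rot, trans = trans)
  op$xyz <- symop_to_xyz(op)
  class(op) <- "symop"
  op
}

#' Serialize a symmetry operator to its xyz string
#'
#' @param op A `symop` (list with `rot` and `trans`).
#' @return Canonical operator string, e.g. `"-x+1/2, y+1/2, -z"`.
#' @export
symop_to_xyz <- function(op) {
  frac_str <- function(t) {
    if (abs(t) < 1e-9) return("")
    for (den in c(2, 3, 4, 6)) {
      num <- t * den
      if (abs(num - round(num)) < 1e-9) {
        return(sprintf("%+d/%d", as.integer(round(num)), den))
      }
    }
    sprintf("%+g", t)
  }
  comps <- vapply(1:3, function(i) {
    out <- ""
    for (j in 1:3) {
      r <- op$rot[i, j]
      if (r != 0) {
        sgn <- if (r > 0) "+" else "-"
        out <- paste0(out, sgn, c("x", "y", "z")[j])
      }
    }
    out <- paste0(out, frac_str(op$trans[i]))
    sub("^\\+", "", out)
  }, character(1))
  paste(comps, collapse = ", ")
}

#' @export
print.symop <- function(x, ...) {
  cat("<symop> ", x$xyz, "\n", sep = "")
  invisible(x)
}

# op1 o op2 acting on fractional coordinates, translation reduced mod 1.
symop_compose <- function(op1, op2) {
  op <- list(rot = op1$rot %*% op2$rot,
             trans = (as.numeric(op1$rot %*% op2$trans) + op1$trans) %% 1)
  op$xyz <- symop_to_xyz(op)
  class(op) <- "symop"
  op
}

symop_is_identity <- function(op) {
  all(op$rot == diag(3)) && all(abs(op$trans %% 1) < 1e-9)
}

# Pure lattice-translation operator (possibly a centering): rotation is the
# identity, translation may be non-zero.
symop_is_translation <- function(op) all(op$rot == diag(3))

symop_key <- function(op) {
  paste(c(op$rot, round(op$trans %% 1, 6)), collapse = ",")
}

#' Check closure of an operator set
#'
#' Verifies that a set of operators is closed under composition modulo lattice
#' translations (a group-sanity check for parsed CIF operator lists).
#'
#' @param ops List of `symop` objects.
#' @return `TRUE` invisibly; stops with a diagnostic if closure fails.
#' @export
validate_operators <- function(ops) {
  keys <- vapply(ops, symop_key, character(1))
  for (i in seq_along(ops)) {
    for (j in seq_along(ops)) {
      k <- symop_key(symop_compose(ops[[i]], ops[[j]]))
      if (!k %in% keys) {
        stop("operator set not closed: ", ops[[i]]$xyz, " o ", ops[[j]]$xyz,
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# Named operator sets for the space groups used by the synthetic generator.
spacegroup_ops <- function(symbol) {
  xyz <- switch(symbol,
    "P1" = "x, y, z",
    "P-1" = c("x, y, z", "-x, -y, -z"),
    "P21/c" = c("x, y, z", "-x, y+1/2, -z+1/2",
                "-x, -y, -z", "x, -y+1/2, z+1/2"),
    "C2/c" = c("x, y, z", "-x, y, -z+1/2", "-x, -y, -z", "x, -y, z+1/2",
               "x+1/2, y+1/2, z", "-x+1/2, y+1/2, -z+1/2",
               "-x+1/2, -y+1/2, -z", "x+1/2, -y+1/2, z+1/2"),
    stop("unknown space-group symbol '", symbol, "'", call. = FALSE)
  )
  lapply(xyz, parse_symop)
}
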