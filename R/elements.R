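# Element property tables.
#
# Atomic weights: IUPAC conventional values (abridged to common organics +
# halogens + a few inorganics). Covalent radii: Cordero et al. single-bond
# radii. Van der Waals radii: Bondi's compilation (Br 1.85, Cl 1.75, C 1.70,
# N 1.55, O 1.52, H 1.20 A).

.element_table <- local({
  tab <- data.frame(
    element = c("H", "D", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P",
                "S", "Cl", "K", "Ca", "Fe", "Cu", "Zn", "Se", "Br", "I"),
    weight = c(1.008, 2.014, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990,
               24.305, 28.085, 30.974, 32.06, 35.45, 39.098, 40.078, 55.845,
               63.546, 65.38, 78.971, 79.904, 126.904),
    r_cov = c(0.31, 0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.11,
              1.07, 1.05, 1.02, 2.03, 1.76, 1.32, 1.32, 1.22, 1.20, 1.20,
              1.39),
    r_vdw = c(1.20, 1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.27, 1.73, 2.10,
              1.80, 1.80, 1.75, 2.75, 2.31, 2.05, 1.40, 1.39, 1.90, 1.85,
              1.98),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$element
  tab
})

.element_lookup <- function(element, column, what) {
  idx <- match(element, .element_table$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    stop("no tabulated ", what, " for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  .element_table[[column]][idx]
}

#' Standard atomic weight of an element
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"Br"`).
#' @return Numeric vector of atomic weights in g/mol.
#' @export
atomic_weight <- function(element) .element_lookup(element, "weight", "atomic weight")

#' Covalent radius of an element
#'
#' Single-bond covalent radii used for bond perception.
#'
#' @inheritParams atomic_weight
#' @return Numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(element) .element_lookup(element, "r_cov", "covalent radius")

#' Van der Waals radius of an element
#'
#' Bondi radii used for close-contact analysis and cluster shell membership.
#'
#' @inheritParams atomic_weight
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) .element_lookup(element, "r_vdw", "van der Waals radius")

#' Is an element symbol known to the package tables?
#'
#' @inheritParams atomic_weight
#' @return Logical vector.
#' @export
is_known_element <- function(element) element %in% .element_table$element

# Strip trailing digits/primes from an atom label to infer the element, e.g.
# "C12" -> "C", "Br1" -> "Br", "H1A" is handled by trying the longest prefix
# that is a known symbol.
element_from_label <- function(label) {
  vapply(label, function(lb) {
    stem <- sub("[^A-Za-z].*$", "", lb)
    for (k in rev(seq_len(min(nchar(stem), 2)))) {
      cand <- substr(stem, 1, k)
      cand <- paste0(toupper(substr(cand, 1, 1)), tolower(substr(cand, 2, k)))
      if (is_known_element(cand)) return(cand)
    }
    stop("cannot infer element from label '", lb, "'", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Molecular weight from an empirical formula
#'
#' Parses an empirical formula string such as `"C15H12BrNO2"` into
#' element--count pairs and sums standard atomic weights.
#'
#' @param formula Empirical formula string. Element symbols with optional
#'   integer counts, e.g. `"C16H13NO2"`, `"H2O"`.
#' @return Formula weight in g/mol.
#' @examples
#' formula_weight("H2O")
#' formula_weight("C15H12BrNO2")
#' @export
formula_weight <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (length(parts) == 0L || paste(parts, collapse = "") != f) {
    stop("cannot parse empirical formula '", formula, "'", call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  sum(atomic_weight(elems) * counts)
}
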