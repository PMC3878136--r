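# Unit-cell metrics: metric tensor, volume, orthogonalization, density, Z.

#' Construct a unit cell
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; each must lie in (0, 180)
#'   and together define a positive-definite metric.
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(19.623, 4.0710, 32.979, 90, 101.698, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = unname(a), b = unname(b), c = unname(c),
            alpha = unname(alpha), beta = unname(beta), gamma = unname(gamma))
  if (any(!is.finite(vals))) stop("cell parameters must be finite", call. = FALSE)
  if (any(vals[1:3] <= 0)) stop("cell lengths must be positive", call. = FALSE)
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  cell <- structure(as.list(vals), class = "unit_cell")
  G <- cell_metric(cell)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("cell angles do not define a positive-definite metric", call. = FALSE)
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Metric tensor of a unit cell
#'
#' G_ij = e_i . e_j for the three cell vectors.
#'
#' @param cell A [unit_cell()].
#' @return A symmetric 3x3 matrix (Angstrom^2).
#' @export
cell_metric <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(a * a,      a * b * cg, a * c * cb,
                      a * b * cg, b * b,      b * c * ca,
                      a * c * cb, b * c * ca, c * c), 3, 3))
}

#' Unit-cell volume
#'
#' V = abc sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g),
#' which reduces to abc sin(beta) for monoclinic and abc for orthogonal cells.
#'
#' @param cell A [unit_cell()].
#' @return Volume in Angstrom^3.
#' @examples
#' cell_volume(unit_cell(19.623, 4.0710, 32.979, 90, 101.698, 90)) # ~2579.8
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) stop("cell metric is not positive definite", call. = FALSE)
  cell$a * cell$b * cell$c * sqrt(arg)
}

#' Orthogonalization matrix of a unit cell
#'
#' Columns are the Cartesian images of the cell vectors in the standard
#' crystallographic frame: a along x, b in the xy-plane.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 matrix M such that `M %*% fract` gives Cartesian Angstrom
#'   coordinates and `t(M) %*% M` equals the metric tensor.
#' @export
cell_orthomatrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- cell_volume(cell)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           v / (cell$a * cell$b * sg)),
         3, 3, byrow = TRUE)
}

#' Fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param fract Numeric length-3 vector, or an n x 3 matrix of fractional
#'   coordinates (rows are points).
#' @return Cartesian coordinates in Angstrom, same shape as the input.
#' @export
frac_to_cart <- function(cell, fract) {
  M <- cell_orthomatrix(cell)
  if (is.matrix(fract)) t(M %*% t(fract)) else as.numeric(M %*% fract)
}

#' Cartesian to fractional coordinates
#'
#' @inheritParams frac_to_cart
#' @param cart Numeric length-3 vector or n x 3 matrix of Cartesian Angstrom
#'   coordinates.
#' @return Fractional coordinates, same shape as the input.
#' @export
cart_to_frac <- function(cell, cart) {
  Mi <- solve(cell_orthomatrix(cell))
  if (is.matrix(cart)) t(Mi %*% t(cart)) else as.numeric(Mi %*% cart)
}

#' Calculated crystal density
#'
#' D = Z M / (N_A V), with V from [cell_volume()] (1 A^3 = 1e-24 cm^3).
#'
#' @param cell A [unit_cell()].
#' @param fw Formula weight in g/mol per formula unit.
#' @param z Formula units per unit cell (integer >= 1).
#' @return Density in g/cm^3.
#' @export
calc_density <- function(cell, fw, z) {
  stopifnot(fw > 0, z >= 1)
  avogadro <- 6.02214076e23
  z * fw / (avogadro * cell_volume(cell) * 1e-24)
}

#' Infer the number of formula units per cell
#'
#' Scans integer Z candidates for the one whose calculated density lies in the
#' physically plausible window for organic solids (0.5-3.5 g/cm^3) and is
#' closest to 1.4 g/cm^3. When the space-group operator count is supplied, Z
#' is crystallographically constrained to multiples of it (plus the
#' half-multiple, to allow molecules on special positions), which resolves the
#' scan unambiguously for ordinary molecular crystals.
#'
#' @param cell A [unit_cell()].
#' @param fw Formula weight in g/mol.
#' @param n_ops Optional number of symmetry operators (general-position
#'   multiplicity) of the space group.
#' @param window Plausible density window in g/cm^3.
#' @return Integer Z. The attribute `"ambiguous"` is `TRUE` when two
#'   candidates in the window have densities within 0.15 g/cm^3 of each other.
#' @export
infer_z <- function(cell, fw, n_ops = NULL, window = c(0.5, 3.5)) {
  stopifnot(fw > 0)
  if (is.null(n_ops)) {
    cand <- 1:16
  } else {
    cand <- unique(sort(c(n_ops / 2, n_ops * (1:4))))
    cand <- cand[cand >= 1 & cand == round(cand)]
  }
  dens <- vapply(cand, function(z) calc_density(cell, fw, z), numeric(1))
  keep <- dens >= window[1] & dens <= window[2]
  if (!any(keep)) {
    stop("no integer Z gives a plausible density in [",
         window[1], ", ", window[2], "] g/cm^3", call. = FALSE)
  }
  cand <- cand[keep]
  dens <- dens[keep]
  pick <- which.min(abs(dens - 1.4))
  z <- as.integer(cand[pick])
  ambiguous <- sum(abs(dens - dens[pick]) < 0.15) > 1
  structure(z, ambiguous = ambiguous)
}
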