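#' Construct a unit cell
#'
#' A unit cell is the atom-free description of a crystal lattice: three edge
#' lengths in angstroms and three inter-axial angles in degrees. Everything in
#' the expansion pipeline (volumes, strain tensors, reduced-cell comparison)
#' derives from these six numbers via the metric tensor.
#'
#' @param a,b,c Cell edge lengths in angstroms; must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees, strictly between 0
#'   and 180. `alpha` is the angle between \strong{b} and \strong{c}, `beta`
#'   between \strong{a} and \strong{c}, `gamma` between \strong{a} and
#'   \strong{b}.
#' @return An object of class `unit_cell`: a named numeric vector
#'   `(a, b, c, alpha, beta, gamma)`.
#' @examples
#' unit_cell(10, 10, 10, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            gamma = as.numeric(gamma))
  validate_unit_cell(cell)
  class(cell) <- "unit_cell"
  cell
}

validate_unit_cell <- function(cell) {
  if (length(cell) != 6 || anyNA(cell)) {
    stop("a unit cell needs six finite parameters (a, b, c, alpha, beta, gamma)")
  }
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees")
  }
  ca <- cos(cell[[4]] * pi / 180)
  cb <- cos(cell[[5]] * pi / 180)
  cg <- cos(cell[[6]] * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) {
    stop("invalid cell: angle combination gives non-positive volume discriminant")
  }
  invisible(cell)
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f (A)  alpha=%.3f beta=%.3f gamma=%.3f (deg)\n",
              x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]]))
  invisible(x)
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  x <- as.numeric(x)
  unit_cell(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' Unit-cell volume
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic angstroms, computed as
#'   \eqn{abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma+
#'   2\cos\alpha\cos\beta\cos\gamma}}.
#' @examples
#' cell_volume(unit_cell(10, 10, 10, 90, 90, 90)) # 1000
#' @export
cell_volume <- function(cell) {
  cell <- as_unit_cell(cell)
  ca <- cos(cell[[4]] * pi / 180)
  cb <- cos(cell[[5]] * pi / 180)
  cg <- cos(cell[[6]] * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("invalid cell: non-positive volume discriminant")
  cell[[1]] * cell[[2]] * cell[[3]] * sqrt(disc)
}

#' Metric tensor of a unit cell
#'
#' The Gram matrix \eqn{G_{ij} = \mathbf{e}_i \cdot \mathbf{e}_j} of the three
#' lattice basis vectors; symmetric positive definite with
#' \eqn{\det G = V^2}.
#'
#' @param cell A [unit_cell()].
#' @return A symmetric 3x3 matrix in square angstroms.
#' @export
metric_tensor <- function(cell) {
  cell <- as_unit_cell(cell)
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  ca <- cos(cell[[4]] * pi / 180)
  cb <- cos(cell[[5]] * pi / 180)
  cg <- cos(cell[[6]] * pi / 180)
  G <- matrix(c(a * a,      a * b * cg, a * cc * cb,
                a * b * cg, b * b,      b * cc * ca,
                a * cc * cb, b * cc * ca, cc * cc), 3, 3)
  dimnames(G) <- NULL
  G
}

#' Unit cell from a metric tensor
#'
#' Inverse of [metric_tensor()]: recovers the six cell parameters from a
#' symmetric positive-definite Gram matrix.
#'
#' @param G A symmetric positive-definite 3x3 matrix (square angstroms).
#' @return A [unit_cell()].
#' @export
cell_from_metric <- function(G) {
  G <- (G + t(G)) / 2
  a <- sqrt(G[1, 1]); b <- sqrt(G[2, 2]); cc <- sqrt(G[3, 3])
  clamp <- function(x) max(-1, min(1, x))
  alpha <- acos(clamp(G[2, 3] / (b * cc))) * 180 / pi
  beta  <- acos(clamp(G[1, 3] / (a * cc))) * 180 / pi
  gamma <- acos(clamp(G[1, 2] / (a * b))) * 180 / pi
  unit_cell(a, b, cc, alpha, beta, gamma)
}

#' Orthogonalization matrix
#'
#' Cartesian basis matrix A whose columns are the lattice vectors
#' \strong{a}, \strong{b}, \strong{c} expressed in a fixed orthonormal frame,
#' so that \eqn{A^\top A = G}. The default (and only built-in) convention is
#' the common crystallographic one: x parallel to \strong{a}, y in the
#' \strong{a}-\strong{b} plane, z along \strong{c*}. Any fixed convention
#' yields identical strain eigenvalues; the convention only fixes how
#' principal-axis vectors are reported.
#'
#' @param cell A [unit_cell()].
#' @param convention Orthogonalization convention; only `"a-along-x"` is
#'   implemented.
#' @return A 3x3 matrix in angstroms with `det(A) = +V`.
#' @export
orthogonalization_matrix <- function(cell, convention = "a-along-x") {
  convention <- match.arg(convention)
  cell <- as_unit_cell(cell)
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  ca <- cos(cell[[4]] * pi / 180)
  cb <- cos(cell[[5]] * pi / 180)
  cg <- cos(cell[[6]] * pi / 180)
  sg <- sin(cell[[6]] * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg) # V / (abc)
  matrix(c(a,  b * cg,            cc * cb,
           0,  b * sg,            cc * (ca - cb * cg) / sg,
           0,  0,                 cc * v / sg), 3, 3, byrow = TRUE)
}

# squared 2-norm of the relative difference between two cells, used only for
# "identical within tolerance" guards
cells_close <- function(cellA, cellB, tol = 1e-8) {
  a <- as.numeric(cellA); b <- as.numeric(cellB)
  all(abs(a - b) <= tol * pmax(abs(a), abs(b), 1))
}
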