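#' Niggli cell reduction
#'
#' Reduces a unit cell to its canonical Niggli form by the Krivy--Gruber
#' iteration with epsilon-stabilised comparisons. The Niggli cell is the unique
#' canonical primitive cell of a lattice, which makes determinations of the
#' same phase comparable regardless of the space-group setting they were
#' published in (e.g. P2\eqn{_1}/c versus P2\eqn{_1}/n).
#'
#' @param cell A [unit_cell()].
#' @param eps Relative tolerance for the stabilised comparisons (dimensionless,
#'   applied on the scale of the squared cell edges).
#' @param max_iter Iteration cap; the stabilised algorithm converges in a few
#'   dozen steps for any physical cell, the cap guards against pathological
#'   cycling on near-degenerate input.
#' @return A list with elements `cell` (the reduced [unit_cell()]),
#'   `transform` (integer 3x3 matrix `M`, `det(M) = +/-1`, such that the
#'   reduced basis is the input basis times `M`), and `iterations`.
#' @references Krivy, I. & Gruber, B. (1976). Acta Cryst. A32, 297-298.
#' @export
niggli_reduce <- function(cell, eps = 1e-5, max_iter = 100) {
  cell <- as_unit_cell(cell)
  if (eps <= 0) stop("eps must be positive")
  G <- metric_tensor(cell)
  A <- G[1, 1]; B <- G[2, 2]; C <- G[3, 3]
  xi <- 2 * G[2, 3]; eta <- 2 * G[1, 3]; zeta <- 2 * G[1, 2]
  e <- eps * det(G)^(1 / 3)
  M <- diag(3)

  # sign classes with the stabilised zero band
  sgn <- function(x) if (x > e) 1L else if (x < -e) -1L else 0L

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("Niggli reduction failed to converge within the iteration cap")
    }
    # A1: order A <= B (swap a, b)
    if (A > B + e || (abs(A - B) <= e && abs(xi) > abs(eta) + e)) {
      tmp <- A; A <- B; B <- tmp
      tmp <- xi; xi <- eta; eta <- tmp
      M <- M %*% matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3)
    }
    # A2: order B <= C (swap b, c)
    if (B > C + e || (abs(B - C) <= e && abs(eta) > abs(zeta) + e)) {
      tmp <- B; B <- C; C <- tmp
      tmp <- eta; eta <- zeta; zeta <- tmp
      M <- M %*% matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3, 3)
      next
    }
    l <- sgn(xi); m <- sgn(eta); n <- sgn(zeta)
    if (l * m * n > 0L) {
      # A3: make all angle terms positive (even number of sign flips)
      f <- c(if (l == -1L) -1 else 1,
             if (m == -1L) -1 else 1,
             if (n == -1L) -1 else 1)
      xi <- f[1] * xi; eta <- f[2] * eta; zeta <- f[3] * zeta
      M <- M %*% diag(f)
    } else {
      # A4: make all angle terms non-positive, keeping det = +1 by spending
      # the free sign on a zero entry if one exists
      f <- c(if (l == 1L) -1 else 1,
             if (m == 1L) -1 else 1,
             if (n == 1L) -1 else 1)
      if (prod(f) < 0) {
        z <- which(c(l, m, n) == 0L)
        if (length(z) == 0L) stop("internal error in Niggli sign normalisation")
        f[z[1]] <- -f[z[1]]
      }
      xi <- f[1] * xi; eta <- f[2] * eta; zeta <- f[3] * zeta
      M <- M %*% diag(f)
    }
    # A5: |xi| <= B
    if (abs(xi) > B + e ||
        (abs(xi - B) <= e && 2 * eta < zeta - e) ||
        (abs(xi + B) <= e && zeta < -e)) {
      s <- sign(xi)
      C <- B + C - s * xi
      eta <- eta - s * zeta
      xi <- xi - 2 * s * B
      M <- M %*% matrix(c(1, 0, 0, 0, 1, 0, 0, -s, 1), 3, 3)
      next
    }
    # A6: |eta| <= A
    if (abs(eta) > A + e ||
        (abs(eta - A) <= e && 2 * xi < zeta - e) ||
        (abs(eta + A) <= e && zeta < -e)) {
      s <- sign(eta)
      C <- A + C - s * eta
      xi <- xi - s * zeta
      eta <- eta - 2 * s * A
      M <- M %*% matrix(c(1, 0, 0, 0, 1, 0, -s, 0, 1), 3, 3)
      next
    }
    # A7: |zeta| <= A
    if (abs(zeta) > A + e ||
        (abs(zeta - A) <= e && 2 * xi < eta - e) ||
        (abs(zeta + A) <= e && eta < -e)) {
      s <- sign(zeta)
      B <- A + B - s * zeta
      xi <- xi - s * eta
      zeta <- zeta - 2 * s * A
      M <- M %*% matrix(c(1, 0, 0, -s, 1, 0, 0, 0, 1), 3, 3)
      next
    }
    # A8: body-diagonal condition
    if (xi + eta + zeta + A + B < -e ||
        (abs(xi + eta + zeta + A + B) <= e && 2 * (A + eta) + zeta > e)) {
      C <- A + B + C + xi + eta + zeta
      xi <- 2 * B + xi + zeta
      eta <- 2 * A + eta + zeta
      M <- M %*% matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 1), 3, 3)
      next
    }
    break
  }

  a <- sqrt(A); b <- sqrt(B); cc <- sqrt(C)
  clamp <- function(x) max(-1, min(1, x))
  out <- unit_cell(a, b, cc,
                   acos(clamp(xi / (2 * b * cc))) * 180 / pi,
                   acos(clamp(eta / (2 * a * cc))) * 180 / pi,
                   acos(clamp(zeta / (2 * a * b))) * 180 / pi)
  storage.mode(M) <- "integer"
  list(cell = out, transform = M, iterations = iter)
}

#' Test whether a cell is already Niggli reduced
#'
#' @param cell A [unit_cell()].
#' @param tol Relative tolerance on cell parameters.
#' @return `TRUE` when [niggli_reduce()] returns the cell unchanged within
#'   `tol`.
#' @export
is_niggli_reduced <- function(cell, tol = 1e-6) {
  red <- niggli_reduce(cell)$cell
  cells_close(cell, red, tol)
}

# the 48 signed axis permutations (basis relabelings that leave a reduced
# cell's main conditions intact up to ordering/sign ties); built once
signed_permutations <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  out <- list()
  for (p in perms) {
    P0 <- diag(3)[, p]
    for (r in seq_len(nrow(signs))) {
      out[[length(out) + 1L]] <- P0 %*% diag(as.numeric(signs[r, ]))
    }
  }
  out
})

# all integer 3x3 matrices with entries in {-1, 0, 1} and det = +/-1: the
# transformations that can relate alternative (near-)reduced bases of one
# lattice across Niggli boundary discontinuities; enumerated on first use
small_unimodular_pool <- local({
  pool <- NULL
  function() {
    if (!is.null(pool)) return(pool)
    grid <- as.matrix(expand.grid(rep(list(-1:1), 9)))
    dets <- grid[, 1] * (grid[, 5] * grid[, 9] - grid[, 6] * grid[, 8]) -
      grid[, 4] * (grid[, 2] * grid[, 9] - grid[, 3] * grid[, 8]) +
      grid[, 7] * (grid[, 2] * grid[, 6] - grid[, 3] * grid[, 5])
    keep <- which(abs(dets) == 1)
    pool <<- lapply(keep, function(i) matrix(grid[i, ], 3, 3))
    pool
  }
})

# minimal lattice deformation between two (reduced) cells, together with the
# basis transformation of cellB realising it. The 48 signed permutations are
# tried first; when their minimum exceeds `full_search_above`, the search is
# extended to the full small-unimodular pool (exact for the decision against
# any threshold >= full_search_above).
lattice_match <- function(cellA, cellB, full_search_above = 0.1) {
  Ainv <- solve(orthogonalization_matrix(cellA))
  GB <- metric_tensor(cellB)
  measure_for <- function(M) {
    FtF <- t(Ainv) %*% t(M) %*% GB %*% M %*% Ainv
    eta <- (FtF - diag(3)) / 2
    sqrt(sum(eta * eta))
  }
  vals <- vapply(signed_permutations, measure_for, numeric(1))
  best <- which.min(vals)
  out <- list(measure = vals[best], transform = signed_permutations[[best]])
  if (out$measure <= full_search_above) return(out)
  for (M in small_unimodular_pool()) {
    v <- measure_for(M)
    if (v < out$measure) out <- list(measure = v, transform = M)
  }
  out
}

#' Metric deformation measure between two reduced cells
#'
#' Scalar similarity measure used to decide whether two determinations belong
#' to the same crystal phase: the Frobenius norm of the finite Lagrangian
#' strain \eqn{\eta = (F^\top F - I)/2} between the two reduced lattice bases,
#' where \eqn{F = A_B A_A^{-1}} maps one orthogonalized basis onto the other.
#' Zero for identical cells, symmetric in its arguments to first order in
#' strain.
#'
#' Niggli reduction is discontinuous at its boundary conditions: a monoclinic
#' lattice with an angle within noise of 90 degrees can flip between the
#' all-acute and all-obtuse settings, near-equal edges can swap order, and a
#' lattice close to a reduction inequality can jump to a shear-related basis.
#' Two determinations of one phase may therefore arrive in formally different
#' (but lattice-equivalent) reduced settings. With `canonicalize = TRUE` (the
#' default) the measure is minimised over lattice-equivalent re-basings of
#' `cellB`: the 48 signed axis permutations first and, when those remain
#' above `full_search_above`, all small unimodular transformations with
#' entries in \{-1, 0, 1\} — which makes the value exact whenever it is
#' compared against a threshold at or above `full_search_above`.
#' `canonicalize = FALSE` gives the plain single-setting value.
#'
#' @param cellA,cellB Niggli-reduced [unit_cell()]s (checked; pass
#'   `check = FALSE` to skip when the caller guarantees reduction).
#' @param check Verify that both cells are reduced before comparing.
#' @param canonicalize Minimise over lattice-equivalent re-basings of `cellB`.
#' @param full_search_above Extend the search beyond signed permutations when
#'   their minimum exceeds this value.
#' @return Dimensionless deformation \eqn{\ge 0}.
#' @export
deformation_measure <- function(cellA, cellB, check = TRUE,
                                canonicalize = TRUE,
                                full_search_above = 0.1) {
  cellA <- as_unit_cell(cellA); cellB <- as_unit_cell(cellB)
  if (check && (!is_niggli_reduced(cellA) || !is_niggli_reduced(cellB))) {
    stop("deformation_measure expects Niggli-reduced cells")
  }
  if (!canonicalize) {
    Ainv <- solve(orthogonalization_matrix(cellA))
    FtF <- t(Ainv) %*% metric_tensor(cellB) %*% Ainv
    eta <- (FtF - diag(3)) / 2
    return(sqrt(sum(eta * eta)))
  }
  lattice_match(cellA, cellB, full_search_above)$measure
}

#' Re-express a reduced cell in the setting best matching a reference
#'
#' Applies the lattice-equivalent re-basing that minimises the deformation
#' measure to the reference, returning a cell of the same lattice whose basis
#' lines up with the reference. Used before strain-tensor construction so
#' that all members of a family share one consistent setting even when
#' Niggli reduction lands them on different sides of a boundary condition.
#'
#' @param cell_ref Reference [unit_cell()].
#' @param cell [unit_cell()] to re-set.
#' @return A [unit_cell()] describing the same lattice as `cell`.
#' @export
match_cell_setting <- function(cell_ref, cell) {
  cell_ref <- as_unit_cell(cell_ref); cell <- as_unit_cell(cell)
  m <- lattice_match(cell_ref, cell, full_search_above = 0.05)
  P <- m$transform
  cell_from_metric(t(P) %*% metric_tensor(cell) %*% P)
}
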