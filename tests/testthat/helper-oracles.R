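# Shared fixtures and independent oracles used across the suite.

# random valid cell, biased away from degenerate angle combinations
random_cell <- function(len_range = c(4, 16), ang_range = c(70, 110)) {
  repeat {
    cl <- try(unit_cell(runif(1, len_range[1], len_range[2]),
                        runif(1, len_range[1], len_range[2]),
                        runif(1, len_range[1], len_range[2]),
                        runif(1, ang_range[1], ang_range[2]),
                        runif(1, ang_range[1], ang_range[2]),
                        runif(1, ang_range[1], ang_range[2])),
              silent = TRUE)
    if (!inherits(cl, "try-error")) return(cl)
  }
}

# random unimodular matrix: product of elementary shears and signed swaps
random_unimodular <- function(n_ops = 3) {
  M <- diag(3)
  for (i in seq_len(n_ops)) {
    op <- sample(3, 1)
    if (op == 1) {            # shear: add +/- one column to another
      j <- sample(3, 2)
      S <- diag(3); S[j[1], j[2]] <- sample(c(-1, 1), 1)
      M <- M %*% S
    } else if (op == 2) {     # swap two columns, negate one (det preserved)
      j <- sample(3, 2)
      S <- diag(3); S[, j] <- S[, rev(j)]; S[, j[1]] <- -S[, j[1]]
      M <- M %*% S
    } else {                  # negate two columns
      j <- sample(3, 2)
      S <- diag(3); S[j[1], j[1]] <- -1; S[j[2], j[2]] <- -1
      M <- M %*% S
    }
  }
  storage.mode(M) <- "integer"
  M
}

# apply an integer basis transformation to a cell
transform_cell <- function(cell, M) {
  G <- metric_tensor(cell)
  cell_from_metric(t(M) %*% G %*% M)
}

# all 3x3 integer matrices with entries in {-1, 0, 1} and det = +/-1,
# enumerated once per test run (brute-force search space for reduction checks)
unimodular_pool <- local({
  pool <- NULL
  function() {
    if (!is.null(pool)) return(pool)
    grid <- as.matrix(expand.grid(rep(list(-1:1), 9)))
    dets <- grid[, 1] * (grid[, 5] * grid[, 9] - grid[, 6] * grid[, 8]) -
      grid[, 4] * (grid[, 2] * grid[, 9] - grid[, 3] * grid[, 8]) +
      grid[, 7] * (grid[, 2] * grid[, 6] - grid[, 3] * grid[, 5])
    keep <- abs(dets) == 1
    pool <<- lapply(which(keep), function(i) matrix(grid[i, ], 3, 3))
    pool
  }
})

# brute-force check: no small re-basing of `cell` yields lexicographically
# smaller sorted edge lengths (the reduced cell is a minimal, Buerger, cell)
brute_force_is_minimal <- function(cell, tol = 1e-8) {
  G <- metric_tensor(cell)
  base <- sort(sqrt(diag(G)))
  for (M in unimodular_pool()) {
    Gp <- t(M) %*% G %*% M
    lens <- sort(sqrt(diag(Gp)))
    for (k in 1:3) {
      if (lens[k] < base[k] - tol * base[k]) return(FALSE)
      if (lens[k] > base[k] + tol * base[k]) break
    }
  }
  TRUE
}

# hand-coded HC1 sandwich estimator for the slope of y ~ 1 + t; the
# regressor is centred (slope and its error are invariant) so the normal
# equations stay well conditioned
hc1_slope_se_oracle <- function(t, y) {
  X <- cbind(1, t - mean(t))
  n <- length(y); k <- ncol(X)
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, y)
  e <- drop(y - X %*% beta)
  meat <- crossprod(X * e)  # t(X) %*% diag(e^2) %*% X
  V <- n / (n - k) * XtXinv %*% meat %*% XtXinv
  sqrt(V[2, 2])
}

# explicit-matrix evaluation of the linear Lagrangian strain via an
# independent (Cholesky) construction of the orthogonalized bases
strain_oracle <- function(cell_ref, cell_t) {
  A_ref <- chol(metric_tensor(cell_ref))
  A_t <- chol(metric_tensor(cell_t))
  Fm <- A_t %*% solve(A_ref)
  (Fm + t(Fm)) / 2 - diag(3)
}

# Rand index between two partitions given as label vectors
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(same_x == same_y)
}

# minimal entry-table row constructor for family-builder tests
make_entry <- function(refcode, cell, temperature_K = NA_real_,
                       r_factor = 0.05, pressure_flag = FALSE,
                       has_coords = TRUE, organic = TRUE, polymeric = FALSE,
                       publication_id = "PUB1") {
  cl <- as.numeric(cell)
  data.frame(refcode = refcode, a = cl[1], b = cl[2], c = cl[3],
             alpha = cl[4], beta = cl[5], gamma = cl[6],
             temperature_K = temperature_K, r_factor = r_factor,
             pressure_flag = pressure_flag, has_coords = has_coords,
             organic = organic, polymeric = polymeric,
             publication_id = publication_id, stringsAsFactors = FALSE)
}

# build a noise-free entry table for one family evolving isotropically
isotropic_family_entries <- function(refroot = "ISOFAM", a0 = 10,
                                     temps = c(100, 200, 293),
                                     rate = 1e-4) {
  rows <- lapply(seq_along(temps), function(i) {
    s <- rate * (temps[i] - temps[1])
    make_entry(sprintf("%s%02d", refroot, i),
               unit_cell(a0 * (1 + s), a0 * (1 + s), a0 * (1 + s), 90, 90, 90),
               temperature_K = temps[i])
  })
  do.call(rbind, rows)
}
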