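test_that("two-point volumetric fit matches the exact line", {
  vf <- volumetric_fit(c(100, 300), c(1000, 1030))
  expect_equal(vf$slope, 0.15)
  expect_equal(vf$v_298, 1029.7)
  expect_equal(vf$alpha_v_298, 1e6 * 0.15 / 1029.7, tolerance = 1e-12)
  expect_equal(round(vf$alpha_v_298, 2), 145.67)
  expect_true(is.na(vf$su_alpha_v))
  expect_true(is.na(vf$r_squared))
})

test_that("collinear series gives r-squared of one; duplicates are refused", {
  # exactly collinear input: lm warns about a perfect fit, which is the point
  vf <- suppressWarnings(
    volumetric_fit(c(100, 150, 200, 250), 1000 + 0.2 * c(100, 150, 200, 250)))
  expect_equal(vf$r_squared, 1)
  expect_equal(vf$alpha_v_298, 1e6 * 0.2 / (1000 + 0.2 * 298), tolerance = 1e-9)
  expect_error(volumetric_fit(c(100, 100, 200), c(1, 2, 3)), "duplicate")
})

test_that("HC1 slope errors match a hand-coded sandwich estimator", {
  set.seed(401)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    t <- sort(runif(n, 90, 300))
    y <- 1000 + 0.2 * t + rnorm(n, 0, 0.05 * (1 + (t - 90) / 100)) # heteroscedastic
    se_oracle <- hc1_slope_se_oracle(t, y)
    expect_equal(thermex:::slope_with_hc_se(t, y)$se, se_oracle,
                 tolerance = 1e-10)
    # and the propagation to alpha_V(298) round-trips to the same estimate
    vf <- volumetric_fit(t, y)
    se_slope <- vf$su_alpha_v * vf$v_298^2 / (1e6 * vf$intercept)
    expect_equal(se_slope, se_oracle, tolerance = 1e-8)
  }
})

test_that("strain tensors match closed forms, symmetry constraints and the matrix oracle", {
  cl <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_equal(strain_tensor_pair(cl, cl), matrix(0, 3, 3))
  e_iso <- strain_tensor_pair(cl, unit_cell(10.2, 10.2, 10.2, 90, 90, 90))
  expect_equal(e_iso, diag(0.02, 3), tolerance = 1e-12)

  # monoclinic b-unique pair differing only in beta: no xy / yz shear and
  # (0,1,0) is an exact eigenvector
  m1 <- unit_cell(6, 8, 10, 90, 100, 90)
  m2 <- unit_cell(6, 8, 10, 90, 101, 90)
  e <- strain_tensor_pair(m1, m2)
  expect_equal(e[1, 2], 0); expect_equal(e[2, 3], 0)
  ev <- eigen(e, symmetric = TRUE)$vectors
  expect_true(any(apply(abs(ev), 2, function(v) isTRUE(all.equal(v, c(0, 1, 0))))))

  set.seed(402)
  for (i in 1:40) {
    ref <- random_cell()
    E <- matrix(rnorm(9, 0, 0.005), 3, 3); E <- (E + t(E)) / 2
    A <- orthogonalization_matrix(ref)
    dest <- cell_from_metric(crossprod((diag(3) + E) %*% A))
    expect_equal(strain_tensor_pair(ref, dest, guard = Inf),
                 strain_oracle(ref, dest), tolerance = 1e-10)
  }

  # the guard refuses cross-polymorph comparison
  expect_error(strain_tensor_pair(unit_cell(5, 9, 11, 90, 101, 90),
                                  unit_cell(7, 9, 9, 90, 113, 90)),
               "different phases")
})

test_that("isotropic closed-form coefficients and the volumetric identity hold", {
  # cubic 10 A at 100 K expanding isotropically to 10.2 A at 300 K
  cells <- rbind(c(10, 10, 10, 90, 90, 90), c(10.2, 10.2, 10.2, 90, 90, 90))
  ser <- strain_series(cells, c(100, 300))
  pf <- principal_fit(ser)
  a_expected <- 1e6 * 1e-4 / (1 + 1e-4 * 198)
  expect_equal(pf$alpha_l, rep(a_expected, 3), tolerance = 1e-9)
  expect_equal(round(pf$alpha_l[1], 2), 98.06)
  vf <- volumetric_fit(c(100, 300), c(1000, 10.2^3))
  expect_equal(round(vf$alpha_v_298, 1), 288.6)
  expect_lt(abs(sum(pf$alpha_l) - vf$alpha_v_298) / vf$alpha_v_298, 0.02)
})

test_that("planted anisotropic slope tensors are recovered through rotation", {
  set.seed(403)
  for (i in 1:20) {
    rates <- sort(runif(3, -3e-5, 3e-4))
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Edot <- Q %*% diag(rates) %*% t(Q)
    ref <- unit_cell(8, 10, 12, 90, 95, 90)
    A <- orthogonalization_matrix(ref)
    temps <- c(100, 150, 200, 250, 293)
    cells <- t(vapply(temps, function(T) {
      as.numeric(cell_from_metric(crossprod(
        (diag(3) + Edot * (T - 100)) %*% A)))
    }, numeric(6)))
    pf <- principal_fit(strain_series(cells, temps, guard = Inf))
    expect_equal(pf$rate_per_K, rates, tolerance = 5e-3)
    # axes mutually orthogonal
    expect_equal(crossprod(pf$axes), diag(3), tolerance = 1e-8)
  }
})

test_that("eigenvalues are invariant under rigid re-orientation of the family", {
  set.seed(404)
  ref <- niggli_reduce(random_cell())$cell
  A <- orthogonalization_matrix(ref)
  rates <- c(-2e-5, 8e-5, 2e-4)
  Edot <- diag(rates)
  temps <- c(100, 180, 260, 293)
  base_cells <- t(vapply(temps, function(T) {
    as.numeric(cell_from_metric(crossprod((diag(3) + Edot * (T - 100)) %*% A)))
  }, numeric(6)))
  pf1 <- principal_fit(strain_series(base_cells, temps, guard = Inf))
  # the same lattice handed over in a re-set basis: cell parameters identical
  # up to the lattice-equivalent setting, so eigenvalues must agree
  M <- random_unimodular(2)
  reset_cells <- t(vapply(seq_along(temps), function(i) {
    as.numeric(niggli_reduce(transform_cell(base_cells[i, ], M))$cell)
  }, numeric(6)))
  pf2 <- principal_fit(strain_series(reset_cells, temps, guard = Inf))
  expect_equal(pf2$rate_per_K, pf1$rate_per_K, tolerance = 1e-6)
})

test_that("monoclinic and orthorhombic symmetry constraints appear in the axes", {
  # monoclinic: one principal axis exactly along b
  temps <- c(100, 160, 220, 293)
  cells <- t(vapply(temps, function(T) {
    c(6 * (1 + 8e-5 * (T - 100)), 8 * (1 + 3e-5 * (T - 100)),
      10 * (1 + 1.2e-4 * (T - 100)), 90, 100 + 0.004 * (T - 100), 90)
  }, numeric(6)))
  pf <- principal_fit(strain_series(cells, temps))
  on_b <- apply(pf$axes, 2, function(v) isTRUE(all.equal(abs(v), c(0, 1, 0))))
  expect_true(any(on_b))
  # orthorhombic: all three axes are the Cartesian axes
  cells_o <- t(vapply(temps, function(T) {
    c(6 * (1 + 8e-5 * (T - 100)), 8 * (1 + 3e-5 * (T - 100)),
      10 * (1 + 1.2e-4 * (T - 100)), 90, 90, 90)
  }, numeric(6)))
  pf_o <- principal_fit(strain_series(cells_o, temps))
  # axes are the Cartesian axes up to eigenvalue ordering
  expect_true(all(apply(abs(pf_o$axes), 2, max) > 1 - 1e-9))
  expect_equal(crossprod(pf_o$axes), diag(3), tolerance = 1e-9)
})

test_that("anisotropy reproduces printed worked values and rejects a zero sum", {
  expect_equal(anisotropy(c(100, 100, 100)), 0)
  expect_equal(anisotropy(c(-254, 160, 228)), 3.575, tolerance = 0.01)
  expect_equal(anisotropy(c(-225, 52, 339)), 3.383, tolerance = 0.01)
  expect_error(anisotropy(c(-100, 40, 60)), "zero denominator")
  expect_equal(anisotropy(c(-100, 40, 61), denominator = "alpha_v",
                          alpha_v = 2), (61 + 100) / 2)
})

test_that("NTE classification counts axes and applies the conclusiveness rule", {
  r <- classify_nte(c(-249, -99, 623), c(34, 22, 64))
  expect_equal(r$nte_class, "biaxial")
  expect_equal(r$conclusive, c(TRUE, TRUE, FALSE))
  expect_equal(classify_nte(c(5, 50, 100))$nte_class, "none")
  r2 <- classify_nte(c(-5, 50, 100), c(8, NA, NA))
  expect_equal(r2$nte_class, "uniaxial")
  expect_false(any(r2$conclusive))
  expect_equal(classify_nte(c(-20, -30, -40))$nte_class, "triaxial")
})
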