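#' Volumetric expansion fit
#'
#' Fits the unit-cell volume linearly against temperature and converts the
#' slope to the volumetric thermal expansion coefficient
#' \eqn{\alpha_V = (1/V)\,\mathrm{d}V/\mathrm{d}T}, referenced to the volume
#' extrapolated to 298 K and reported in p.p.m. K\eqn{^{-1}}. For three or
#' more points an unweighted ordinary least-squares fit is used and the slope
#' uncertainty is the heteroscedasticity-consistent (HC1 sandwich) standard
#' error, propagated to \eqn{\alpha_V(298)} at first order. For exactly two
#' points the line is exact and no uncertainty is available.
#'
#' @param temperature_K,volume_A3 Paired temperatures (K) and volumes
#'   (\eqn{\mathrm{\AA}^3}); at least two points with distinct temperatures.
#' @param hc_type Heteroscedasticity-consistent covariance variant passed to
#'   [sandwich::vcovHC()].
#' @return A list of class `volume_fit`: `slope` (\eqn{\mathrm{\AA}^3}/K),
#'   `intercept`, `r_squared` (`NA` for two points), `alpha_v_298`
#'   (p.p.m. K\eqn{^{-1}}), `su_alpha_v`, `v_298`, `n_points`, `t_min`,
#'   `t_max`.
#' @export
volumetric_fit <- function(temperature_K, volume_A3, hc_type = "HC1") {
  t <- as.numeric(temperature_K); v <- as.numeric(volume_A3)
  if (length(t) != length(v) || length(t) < 2) {
    stop("volumetric_fit needs at least two (T, V) pairs")
  }
  if (anyDuplicated(t)) {
    stop("duplicate temperatures: deduplicate the family before fitting")
  }
  n <- length(t)
  if (n == 2) {
    slope <- diff(v) / diff(t)
    intercept <- v[1] - slope * t[1]
    r2 <- NA_real_
    se_slope <- NA_real_
  } else {
    fit <- stats::lm(v ~ t)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    # near-exact series are routine (noise-free synthetic families); the
    # perfect-fit warning from summary.lm is not informative here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    se_slope <- suppressWarnings(
      sqrt(sandwich::vcovHC(fit, type = hc_type)[2, 2]))
  }
  v298 <- intercept + 298 * slope
  if (v298 <= 0) stop("extrapolated V(298 K) is non-positive; fit is unphysical")
  alpha <- 1e6 * slope / v298
  # first-order propagation of the slope error through alpha = s / (i + 298 s)
  su <- if (is.na(se_slope)) NA_real_ else 1e6 * intercept * se_slope / v298^2
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 alpha_v_298 = alpha, su_alpha_v = su, v_298 = v298,
                 n_points = n, t_min = min(t), t_max = max(t)),
            class = "volume_fit")
}

#' Linear Lagrangian strain between two cells
#'
#' Strain tensor of a deformed cell relative to a reference cell of the same
#' phase, in the linear (infinitesimal) Lagrangian form
#' \eqn{e = \tfrac{1}{2}(F + F^\top) - I}, where
#' \eqn{F = A(\mathrm{cell}_t)\,A(\mathrm{cell}_{ref})^{-1}} is the
#' deformation gradient between the orthogonalized bases. Both cells must be
#' in consistent (reduced, identically oriented) settings; a deformation-
#' measure guard refuses pairs so different that they cannot be the same
#' phase.
#'
#' @param cell_ref,cell_t Reference and deformed [unit_cell()]s.
#' @param guard Maximum admissible deformation measure between the cells;
#'   `Inf` disables the check.
#' @return A symmetric, dimensionless 3x3 strain matrix (zero for identical
#'   cells).
#' @export
strain_tensor_pair <- function(cell_ref, cell_t, guard = 0.12) {
  cell_ref <- as_unit_cell(cell_ref); cell_t <- as_unit_cell(cell_t)
  if (is.finite(guard)) {
    d <- deformation_measure(cell_ref, cell_t, check = FALSE)
    if (d > guard) {
      stop(sprintf(paste0("cells differ by deformation measure %.3f > %.3f: ",
                          "refusing to compare what look like different phases"),
                   d, guard))
    }
  }
  Fm <- orthogonalization_matrix(cell_t) %*%
    solve(orthogonalization_matrix(cell_ref))
  (Fm + t(Fm)) / 2 - diag(3)
}

#' Strain series of a structure family
#'
#' Strain tensors of every determination relative to the family's
#' lowest-temperature structure (the reference, which carries an exactly zero
#' tensor).
#'
#' @param cells List (or 6-column matrix) of reduced cells, one per
#'   determination.
#' @param temperature_K Temperatures matching `cells`.
#' @param guard Deformation-measure guard passed to [strain_tensor_pair()].
#' @return A list of class `strain_series`: `reference_temperature`,
#'   `temperature_K` (sorted ascending) and `strain` (list of symmetric 3x3
#'   matrices).
#' @export
strain_series <- function(cells, temperature_K, guard = 0.12) {
  if (is.matrix(cells)) cells <- lapply(seq_len(nrow(cells)), function(i) cells[i, ])
  t <- as.numeric(temperature_K)
  if (length(cells) != length(t) || length(t) < 2) {
    stop("strain_series needs at least two determinations")
  }
  ord <- order(t)
  t <- t[ord]; cells <- cells[ord]
  ref <- as_unit_cell(cells[[1]])
  strains <- lapply(cells, function(cl) {
    strain_tensor_pair(ref, match_cell_setting(ref, cl), guard = guard)
  })
  strains[[1]] <- matrix(0, 3, 3) # reference strain is exactly zero
  structure(list(reference_temperature = t[1], temperature_K = t,
                 strain = strains), class = "strain_series")
}

# slope and HC standard error of a simple linear fit y ~ t (free intercept)
slope_with_hc_se <- function(t, y, hc_type = "HC1") {
  fit <- stats::lm(y ~ t)
  list(slope = unname(stats::coef(fit)[2]),
       se = suppressWarnings(
         sqrt(sandwich::vcovHC(fit, type = hc_type)[2, 2])))
}

#' Principal expansion coefficients from a strain series
#'
#' Fits each of the six independent strain-tensor components linearly against
#' temperature (free intercept, reference point included) and diagonalises
#' the fitted slope tensor \eqn{\mathrm{d}e/\mathrm{d}T}. The eigenvalues are
#' length-change rates per kelvin along the orthogonal principal axes,
#' referenced to the lowest-temperature structure; they are converted to
#' 298 K by \eqn{\alpha(298) = 10^6 k / (1 + k\,(298 - T_{ref}))}. Per-axis
#' uncertainties come from an HC1 fit of the strain projected onto each fixed
#' eigenvector against temperature. Two-point families use the single
#' available strain tensor divided by the temperature step and carry no
#' uncertainties.
#'
#' @param series A [strain_series()].
#' @param hc_type HC covariance variant for the per-axis uncertainty fits.
#' @return A list of class `principal_fit`: `alpha_l` (three coefficients in
#'   p.p.m. K\eqn{^{-1}}, ascending), `su_l` (matching s.u.s, `NA` for
#'   two-point families), `axes` (3x3 matrix, unit eigenvectors in columns),
#'   `rate_per_K` (raw eigenvalues of the slope tensor) and
#'   `reference_temperature`.
#' @export
principal_fit <- function(series, hc_type = "HC1") {
  stopifnot(inherits(series, "strain_series"))
  t <- series$temperature_K
  n <- length(t)
  comp <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  if (n == 2) {
    Edot <- series$strain[[2]] / (t[2] - t[1])
  } else {
    Edot <- matrix(0, 3, 3)
    for (r in seq_len(nrow(comp))) {
      i <- comp[r, 1]; j <- comp[r, 2]
      y <- vapply(series$strain, function(s) s[i, j], numeric(1))
      k <- unname(stats::coef(stats::lm(y ~ t))[2])
      Edot[i, j] <- k; Edot[j, i] <- k
    }
  }
  eig <- eigen(Edot, symmetric = TRUE)
  ord <- order(eig$values) # ascending
  rates <- eig$values[ord]
  axes <- eig$vectors[, ord, drop = FALSE]
  # reporting convention: make the largest-magnitude component of each axis positive
  for (k in 1:3) {
    lead <- which.max(abs(axes[, k]))
    if (axes[lead, k] < 0) axes[, k] <- -axes[, k]
  }
  dT <- 298 - series$reference_temperature
  to_298 <- function(k) 1e6 * k / (1 + k * dT)
  alpha <- vapply(rates, to_298, numeric(1))
  su <- rep(NA_real_, 3)
  if (n >= 3) {
    for (k in 1:3) {
      v <- axes[, k]
      proj <- vapply(series$strain, function(s) drop(v %*% s %*% v), numeric(1))
      se_k <- slope_with_hc_se(t, proj, hc_type)$se
      # first-order propagation through the 298 K referencing
      su[k] <- 1e6 * se_k / (1 + rates[k] * dT)^2
    }
  }
  structure(list(alpha_l = alpha, su_l = su, axes = axes, rate_per_K = rates,
                 reference_temperature = series$reference_temperature),
            class = "principal_fit")
}

#' Thermal expansion anisotropy
#'
#' Dimensionless spread of the principal coefficients,
#' \eqn{(\alpha_L^{max} - \alpha_L^{min}) / \Sigma\alpha_L}. The volumetric
#' coefficient can be substituted as the denominator. Negative values can
#' only arise from a negative denominator and are flagged invalid downstream.
#'
#' @param alpha_l Three principal coefficients (p.p.m. K\eqn{^{-1}}).
#' @param denominator `"sum_alpha_l"` (default) or `"alpha_v"`.
#' @param alpha_v Volumetric coefficient, required when
#'   `denominator = "alpha_v"`.
#' @return The anisotropy measure.
#' @export
anisotropy <- function(alpha_l, denominator = c("sum_alpha_l", "alpha_v"),
                       alpha_v = NULL) {
  denominator <- match.arg(denominator)
  if (length(alpha_l) != 3) stop("alpha_l must contain three coefficients")
  den <- if (denominator == "alpha_v") {
    if (is.null(alpha_v)) stop("alpha_v required for denominator = 'alpha_v'")
    alpha_v
  } else {
    sum(alpha_l)
  }
  if (den == 0) stop("anisotropy undefined: zero denominator")
  (max(alpha_l) - min(alpha_l)) / den
}

#' Classify negative thermal expansion
#'
#' Counts negative principal coefficients: none, uniaxial (one), biaxial
#' (two) or triaxial (three) NTE. A negative axis is "conclusive" when its
#' coefficient is substantially negative (below `substantial`, default
#' \eqn{-10} p.p.m. K\eqn{^{-1}}) and remains negative within one standard
#' uncertainty; when no s.u. is available (two-point families) only the
#' magnitude criterion applies.
#'
#' @param alpha_l Three principal coefficients (p.p.m. K\eqn{^{-1}}).
#' @param su_l Matching standard uncertainties (`NA` when unavailable).
#' @param substantial Threshold below which a negative coefficient counts as
#'   substantial.
#' @return A list: `nte_class` (`"none"`, `"uniaxial"`, `"biaxial"`,
#'   `"triaxial"`), `n_negative`, and `conclusive` (logical per axis, `FALSE`
#'   for non-negative axes).
#' @export
classify_nte <- function(alpha_l, su_l = rep(NA_real_, 3), substantial = -10) {
  if (length(alpha_l) != 3) stop("alpha_l must contain three coefficients")
  neg <- alpha_l < 0
  conclusive <- neg & (alpha_l < substantial) &
    (is.na(su_l) | alpha_l + su_l < 0)
  list(nte_class = c("none", "uniaxial", "biaxial", "triaxial")[sum(neg) + 1L],
       n_negative = sum(neg), conclusive = conclusive)
}

#' Fit the full expansion result for one structure family
#'
#' The per-family computation of the survey: a volumetric fit of the reduced
#' cell volume against temperature, a principal-axis fit of the linear
#' Lagrangian strain series, the anisotropy measure and the NTE class.
#'
#' @param family A filtered `structure_family` whose entries carry reduced
#'   cells (`red_*` columns, as produced by [build_families()]), or any entry
#'   table with cell parameters and temperatures (cells are then reduced
#'   here).
#' @param config A [survey_config()].
#' @return A list of class `expansion_result` with elements `family_id`,
#'   `volume` (a `volume_fit`), `principal` (a `principal_fit`),
#'   `anisotropy`, `nte` ([classify_nte()] output), `two_point` and
#'   `n_points`.
#' @export
fit_family_expansion <- function(family, config = survey_config()) {
  if (!inherits(family, "structure_family")) stop("expected a structure_family")
  e <- family$entries
  if (!all(c("red_a", "red_b", "red_c") %in% names(e))) {
    e <- reduce_entry_cells(e)
    e <- e[e$reduced, , drop = FALSE]
  }
  cells <- as.matrix(e[, c("red_a", "red_b", "red_c",
                           "red_alpha", "red_beta", "red_gamma")])
  t <- e$temperature_K
  vols <- apply(cells, 1, cell_volume)
  vol <- volumetric_fit(t, vols, hc_type = config$hc_type)
  ser <- strain_series(cells, t, guard = config$strain_guard)
  pr <- principal_fit(ser, hc_type = config$hc_type)
  aniso <- tryCatch(
    anisotropy(pr$alpha_l, denominator = config$anisotropy_denominator,
               alpha_v = vol$alpha_v_298),
    error = function(e) NA_real_)
  structure(list(family_id = family$family_id, volume = vol, principal = pr,
                 anisotropy = aniso,
                 nte = classify_nte(pr$alpha_l, pr$su_l,
                                    config$nte_substantial),
                 two_point = vol$n_points == 2, n_points = vol$n_points),
            class = "expansion_result")
}

#' Flatten expansion results to a table
#'
#' @param results List of `expansion_result` objects.
#' @return A data.frame with one row per family: volumetric and principal
#'   coefficients with uncertainties, principal-axis vectors, anisotropy and
#'   NTE class (the per-family output record of the survey).
#' @export
expansion_results_table <- function(results) {
  rows <- lapply(results, function(r) {
    ax <- r$principal$axes
    data.frame(family_id = r$family_id, n_points = r$n_points,
               t_min = r$volume$t_min, t_max = r$volume$t_max,
               alpha_v = r$volume$alpha_v_298, su_alpha_v = r$volume$su_alpha_v,
               r2_v = r$volume$r_squared,
               alpha_l1 = r$principal$alpha_l[1],
               alpha_l2 = r$principal$alpha_l[2],
               alpha_l3 = r$principal$alpha_l[3],
               su_l1 = r$principal$su_l[1], su_l2 = r$principal$su_l[2],
               su_l3 = r$principal$su_l[3],
               axis1_x = ax[1, 1], axis1_y = ax[2, 1], axis1_z = ax[3, 1],
               axis2_x = ax[1, 2], axis2_y = ax[2, 2], axis2_z = ax[3, 2],
               axis3_x = ax[1, 3], axis3_y = ax[2, 3], axis3_z = ax[3, 3],
               anisotropy = r$anisotropy, nte_class = r$nte$nte_class,
               two_point = r$two_point, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}
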