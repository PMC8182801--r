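#' Skew-normal density
#'
#' Density of the three-parameter skew-normal distribution,
#' \eqn{f(x) = (2/\omega)\,\phi(z)\,\Phi(\alpha z)} with
#' \eqn{z = (x - \xi)/\omega}; reduces to the normal density at `shape = 0`.
#'
#' @param x Evaluation points.
#' @param location,scale,shape Location \eqn{\xi}, scale \eqn{\omega > 0} and
#'   shape \eqn{\alpha}.
#' @return Density values.
#' @export
dskewnorm <- function(x, location = 0, scale = 1, shape = 0) {
  if (scale <= 0) stop("scale must be positive")
  z <- (x - location) / scale
  2 / scale * stats::dnorm(z) * stats::pnorm(shape * z)
}

#' Build a fixed-width histogram
#'
#' Half-open bins `[k*w, (k+1)*w)` anchored at `anchor`, the binning used for
#' all coefficient distributions in the survey (default width
#' 25 p.p.m. K\eqn{^{-1}}).
#'
#' @param values Finite numeric values.
#' @param bin_width Bin width, in the units of `values`.
#' @param anchor Origin of the bin grid.
#' @return A list of class `coef_histogram`: `bin_edges` (length
#'   `n_bins + 1`), `mid` (bin midpoints), `counts`, `n`, `bin_width`.
#' @export
build_histogram <- function(values, bin_width = 25, anchor = 0) {
  values <- values[is.finite(values)]
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(values) == 0) {
    return(structure(list(bin_edges = numeric(0), mid = numeric(0),
                          counts = integer(0), n = 0L, bin_width = bin_width),
                     class = "coef_histogram"))
  }
  idx <- floor((values - anchor) / bin_width)
  lo <- min(idx); hi <- max(idx)
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo + 1L)
  edges <- anchor + (lo:(hi + 1L)) * bin_width
  structure(list(bin_edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = as.integer(counts), n = length(values),
                 bin_width = bin_width),
            class = "coef_histogram")
}

#' Fit a normal curve to histogram counts
#'
#' Nonlinear least squares of `amplitude * dnorm(mid; mean, sd)` against the
#' bin counts at bin midpoints, over the full range of the histogram. The
#' free amplitude decouples the recovered shape from the bin-count scaling;
#' at a perfect fit it equals `n * bin_width`.
#'
#' @param hist A [build_histogram()] result with at least 4 non-empty bins.
#' @return A list of class `distribution_fit` with `family = "normal"`,
#'   `mean`, `sd`, `amplitude` and `rss` (residual sum of squares over bins).
#' @export
fit_normal_to_histogram <- function(hist) {
  check_fittable_histogram(hist)
  x <- hist$mid; y <- hist$counts
  m0 <- sum(x * y) / sum(y)
  s0 <- sqrt(sum((x - m0)^2 * y) / sum(y))
  if (s0 <= 0) stop("degenerate histogram: zero spread")
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * stats::dnorm(x, m, s),
                      start = list(A = hist$n * hist$bin_width, m = m0, s = s0),
                      lower = c(A = 0, m = -Inf, s = hist$bin_width / 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("normal histogram fit failed: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  structure(list(family = "normal", mean = unname(p["m"]), sd = unname(p["s"]),
                 amplitude = unname(p["A"]),
                 rss = sum(stats::resid(fit)^2)),
            class = "distribution_fit")
}

#' Fit a skew-normal curve to histogram counts
#'
#' As [fit_normal_to_histogram()] but with the three-parameter skew-normal
#' density ([dskewnorm()]) plus a free amplitude. Used for the principal
#' coefficient and anisotropy distributions, which are visibly skewed.
#'
#' @param hist A [build_histogram()] result with at least 4 non-empty bins.
#' @return A `distribution_fit` with `family = "skew_normal"`: `location`,
#'   `scale`, `shape`, `amplitude`, `rss`.
#' @export
fit_skew_normal_to_histogram <- function(hist) {
  check_fittable_histogram(hist)
  x <- hist$mid; y <- hist$counts
  m0 <- sum(x * y) / sum(y)
  s0 <- sqrt(sum((x - m0)^2 * y) / sum(y))
  if (s0 <= 0) stop("degenerate histogram: zero spread")
  skew0 <- sum((x - m0)^3 * y) / sum(y) / s0^3
  a0 <- sign(skew0) * 2
  if (a0 == 0) a0 <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * dskewnorm(x, xi, om, al),
                      start = list(A = hist$n * hist$bin_width,
                                   xi = m0 - sign(skew0) * s0 / 2, om = s0,
                                   al = a0),
                      lower = c(A = 0, xi = -Inf, om = hist$bin_width / 100,
                                al = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("skew-normal histogram fit failed: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  structure(list(family = "skew_normal", location = unname(p["xi"]),
                 scale = unname(p["om"]), shape = unname(p["al"]),
                 amplitude = unname(p["A"]),
                 rss = sum(stats::resid(fit)^2)),
            class = "distribution_fit")
}

check_fittable_histogram <- function(hist) {
  if (!inherits(hist, "coef_histogram")) stop("expected a coef_histogram")
  if (sum(hist$counts > 0) < 4) {
    stop("histogram fit needs at least 4 non-empty bins")
  }
  invisible(hist)
}

#' Two-half-normal approximation of a skew-normal fit
#'
#' Summarises an asymmetric fitted curve by a piecewise density that is easy
#' to quote and to turn into one-sided k-sigma thresholds: two half-normal
#' curves sharing the mode of the fitted skew-normal and its peak height,
#' with separate standard deviations fitted by least squares to the
#' skew-normal curve on each side of the mode. The composite density is
#' continuous (and equal to the skew-normal) at the centre by construction.
#'
#' @param skew_fit A converged `distribution_fit` of family `"skew_normal"`.
#' @param n_grid Grid points per side for the least-squares match.
#' @return A `distribution_fit` with `family = "two_half_normal"`: `centre`,
#'   `sd_lower`, `sd_upper`, `amplitude` (peak height including the
#'   skew-normal amplitude), `rss`.
#' @export
half_normal_approx <- function(skew_fit, n_grid = 400) {
  if (!identical(skew_fit$family, "skew_normal")) {
    stop("half_normal_approx expects a skew_normal distribution_fit")
  }
  xi <- skew_fit$location; om <- skew_fit$scale; al <- skew_fit$shape
  A <- skew_fit$amplitude
  dens <- function(x) A * dskewnorm(x, xi, om, al)
  opt <- stats::optimize(dens, interval = c(xi - 5 * om, xi + 5 * om),
                         maximum = TRUE, tol = 1e-10 * om)
  centre <- opt$maximum
  peak <- opt$objective
  fit_side <- function(side) {
    xs <- centre + side * seq(0, 5 * om, length.out = n_grid)
    target <- dens(xs)
    obj <- function(s) sum((peak * exp(-(xs - centre)^2 / (2 * s^2)) - target)^2)
    stats::optimize(obj, interval = c(om / 100, 10 * om), tol = 1e-9 * om)
  }
  lo <- fit_side(-1); up <- fit_side(+1)
  structure(list(family = "two_half_normal", centre = centre,
                 sd_lower = lo$minimum, sd_upper = up$minimum,
                 amplitude = peak, rss = lo$objective + up$objective),
            class = "distribution_fit")
}

#' k-sigma exceptionality thresholds
#'
#' Bounds outside which a coefficient is called exceptional at the k-sigma
#' level: `mean +/- k*sd` for a normal fit, and the one-sided
#' `(centre - k*sd_lower, centre + k*sd_upper)` for a two-half-normal fit.
#'
#' @param fit A `distribution_fit` of family `"normal"` or
#'   `"two_half_normal"`.
#' @param k Sigma multiple.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
sigma_thresholds <- function(fit, k = 3) {
  if (!inherits(fit, "distribution_fit")) stop("expected a distribution_fit")
  if (k < 0) stop("k must be non-negative")
  switch(fit$family,
    normal = c(lower = fit$mean - k * fit$sd, upper = fit$mean + k * fit$sd),
    two_half_normal = c(lower = fit$centre - k * fit$sd_lower,
                        upper = fit$centre + k * fit$sd_upper),
    stop("no sigma thresholds defined for family '", fit$family, "'"))
}

#' Screen families on linearity of the volume expansion
#'
#' Partitions families by the R-squared of the linear volume-temperature fit.
#' Failures carry per-point residual diagnostics so the worst-fitting
#' determination (a mis-reported temperature, an unflagged pressure point, a
#' phase transition) can be identified and, where justified, removed.
#'
#' @param families List of `structure_family` with at least 3 entries each
#'   (R-squared is meaningless for two points; two-point families are
#'   silently skipped).
#' @param r2_min R-squared acceptance threshold.
#' @param config A [survey_config()].
#' @return A list with `passed` (families), `failed` (list of lists:
#'   `family`, `r_squared`, `diagnostics` data.frame with per-point
#'   residuals, largest absolute residual first) and `skipped_two_point`.
#' @export
linearity_screen <- function(families, r2_min = 0.96, config = survey_config()) {
  passed <- list(); failed <- list(); skipped <- list()
  for (fam in families) {
    e <- fam$entries
    if (nrow(e) < 3) { skipped[[length(skipped) + 1L]] <- fam; next }
    cells <- as.matrix(e[, c("red_a", "red_b", "red_c",
                             "red_alpha", "red_beta", "red_gamma")])
    vols <- apply(cells, 1, cell_volume)
    fit <- stats::lm(vols ~ e$temperature_K)
    r2 <- summary(fit)$r.squared
    if (r2 > r2_min) {
      passed[[length(passed) + 1L]] <- fam
    } else {
      diag <- data.frame(refcode = e$refcode,
                         temperature_K = e$temperature_K,
                         volume_A3 = vols,
                         residual_A3 = stats::resid(fit),
                         stringsAsFactors = FALSE)
      diag <- diag[order(-abs(diag$residual_A3)), ]
      failed[[length(failed) + 1L]] <- list(family = fam, r_squared = r2,
                                            diagnostics = diag)
    }
  }
  list(passed = passed, failed = failed, skipped_two_point = skipped)
}

#' Tabulate outlying families
#'
#' Emits the survey's outlier tables: (i) families above the upper
#' volumetric threshold that rest on enough temperature points to be taken
#' seriously; (ii) families at or below the lower threshold, where two-point
#' families are flagged suspect (apparent negative expansion from two points
#' is, in this data model, almost always an unflagged pressure point or a
#' mis-reported temperature); (iii) extreme-anisotropy families backed by a
#' good linear volume fit.
#'
#' @param results_table Output of [expansion_results_table()].
#' @param thresholds `c(lower, upper)` for the volumetric coefficient, from
#'   [sigma_thresholds()].
#' @param min_points Minimum temperature points for table (i) and (iii).
#' @param anisotropy_ref Reference anisotropy that table (iii) must exceed.
#' @param r2_min Linear-fit quality required in table (iii).
#' @return A list of data.frames: `high_alpha_v`, `low_alpha_v` (with a
#'   `suspect` column), `extreme_anisotropy`.
#' @export
tabulate_outliers <- function(results_table, thresholds, min_points = 4,
                              anisotropy_ref = 3.2, r2_min = 0.96) {
  rt <- results_table
  if (nrow(rt) == 0) {
    empty <- rt
    return(list(high_alpha_v = empty, low_alpha_v = empty,
                extreme_anisotropy = empty))
  }
  hi <- rt[rt$alpha_v > thresholds[["upper"]] & rt$n_points >= min_points, ,
           drop = FALSE]
  hi <- hi[order(-hi$alpha_v), , drop = FALSE]
  lo <- rt[rt$alpha_v <= thresholds[["lower"]], , drop = FALSE]
  if (nrow(lo) > 0) lo$suspect <- lo$two_point
  else lo$suspect <- logical(0)
  lo <- lo[order(lo$alpha_v), , drop = FALSE]
  an <- rt[is.finite(rt$anisotropy) & rt$anisotropy > anisotropy_ref &
             rt$n_points >= min_points &
             !is.na(rt$r2_v) & rt$r2_v > r2_min, , drop = FALSE]
  an <- an[order(-an$anisotropy), , drop = FALSE]
  list(high_alpha_v = hi, low_alpha_v = lo, extreme_anisotropy = an)
}
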