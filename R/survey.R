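#' Survey configuration
#'
#' All tunable parameters of the expansion survey, with defaults matching the
#' curation and reporting conventions the pipeline is built around: a 0.12
#' deformation-measure tolerance for family membership, a 90-300 K analysis
#' window with a representative required at 273 K or above and a minimum 50 K
#' span, a 10 K deduplication tolerance, 293 K for unrecorded room
#' temperature, an R-squared screen at 0.96, 25 p.p.m. K\eqn{^{-1}} histogram
#' bins and 3-sigma exceptionality thresholds.
#'
#' @param deformation_tol Deformation-measure acceptance threshold for
#'   reduced-cell family membership.
#' @param temperature_window_K Inclusive analysis window in kelvin.
#' @param min_top_K Required maximum family temperature.
#' @param min_range_K Required family temperature span.
#' @param dedup_tol_K Temperature tolerance when collapsing redeterminations.
#' @param room_temperature_K Temperature assigned to entries with no recorded
#'   value.
#' @param r2_min R-squared threshold of the linearity screen.
#' @param bin_width Histogram bin width, p.p.m. K\eqn{^{-1}}.
#' @param sigma_k Sigma multiple for exceptionality thresholds.
#' @param hc_type Heteroscedasticity-consistent covariance variant for slope
#'   uncertainties.
#' @param anisotropy_denominator `"sum_alpha_l"` or `"alpha_v"`.
#' @param strain_guard Maximum deformation measure admitted between members of
#'   a family when building strain tensors.
#' @param nte_substantial Threshold (p.p.m. K\eqn{^{-1}}) below which a
#'   negative coefficient is substantial.
#' @param single_pub_min_n Minimum entries for the single-publication subset.
#' @param outlier_min_points Minimum temperature points for the outlier
#'   tables.
#' @param anisotropy_ref Anisotropy that table of extremes must exceed.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(deformation_tol = 0.12,
                          temperature_window_K = c(90, 300),
                          min_top_K = 273,
                          min_range_K = 50,
                          dedup_tol_K = 10,
                          room_temperature_K = 293,
                          r2_min = 0.96,
                          bin_width = 25,
                          sigma_k = 3,
                          hc_type = "HC1",
                          anisotropy_denominator = c("sum_alpha_l", "alpha_v"),
                          strain_guard = 0.12,
                          nte_substantial = -10,
                          single_pub_min_n = 4,
                          outlier_min_points = 4,
                          anisotropy_ref = 3.2) {
  cfg <- list(deformation_tol = deformation_tol,
              temperature_window_K = as.numeric(temperature_window_K),
              min_top_K = min_top_K, min_range_K = min_range_K,
              dedup_tol_K = dedup_tol_K,
              room_temperature_K = room_temperature_K, r2_min = r2_min,
              bin_width = bin_width, sigma_k = sigma_k, hc_type = hc_type,
              anisotropy_denominator = match.arg(anisotropy_denominator),
              strain_guard = strain_guard, nte_substantial = nte_substantial,
              single_pub_min_n = single_pub_min_n,
              outlier_min_points = outlier_min_points,
              anisotropy_ref = anisotropy_ref)
  stopifnot(cfg$deformation_tol > 0, length(cfg$temperature_window_K) == 2,
            cfg$dedup_tol_K >= 0, cfg$bin_width > 0, cfg$sigma_k >= 0)
  class(cfg) <- "survey_config"
  cfg
}

#' Serialise / restore a survey configuration
#'
#' @param config A [survey_config()].
#' @param path File to write to / read from.
#' @return `write_survey_config` returns `path` invisibly;
#'   `read_survey_config` returns the restored `survey_config`
#'   (round-trip identity).
#' @export
write_survey_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_survey_config
#' @export
read_survey_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(survey_config, raw)
}

#' Run the full expansion survey
#'
#' End-to-end pipeline on a conforming entry table: constraint screening,
#' reduced-cell family building, temperature deduplication and filtering,
#' per-family volumetric and principal-axis expansion fits, and the
#' population statistics (histograms, distribution fits, k-sigma thresholds,
#' NTE counts, outlier tables). Every discarded entry or family appears in
#' the run log with a machine-readable reason code; the survey itself is
#' deterministic.
#'
#' @param entries An entry table ([read_entries_csv()] schema) or path to its
#'   CSV.
#' @param config A [survey_config()].
#' @return A list of class `expansion_survey`: `results` (list of
#'   `expansion_result`), `results_table`, `families`, `fits` (distribution
#'   fits and thresholds for the volumetric coefficient, the pooled principal
#'   coefficients and the anisotropy measure), `nte` (counts and fractions),
#'   `screen` (linearity-screen partition), `outliers`, `log`,
#'   `family_size_spectrum` and `config`.
#' @export
run_survey <- function(entries, config = survey_config()) {
  if (is.character(entries)) entries <- read_entries_csv(entries)
  n_input <- nrow(entries)
  if (n_input == 0) {
    warning("empty entry table: survey outputs are empty")
  }
  built <- build_families(entries, config)
  log <- built$log
  results <- list(); fitted_families <- list()
  for (fam in built$families) {
    res <- tryCatch(fit_family_expansion(fam, config), error = function(e) e)
    if (inherits(res, "error")) {
      log <- rbind(log, data.frame(id = fam$family_id, stage = "fit",
                                   reason = "strain_guard",
                                   n_entries = fam$n_entries,
                                   stringsAsFactors = FALSE))
    } else {
      results[[length(results) + 1L]] <- res
      fitted_families[[length(fitted_families) + 1L]] <- fam
    }
  }
  built$families <- fitted_families
  rt <- expansion_results_table(results)

  try_fit <- function(expr) tryCatch(expr, error = function(e) NULL)
  fits <- list()
  if (nrow(rt) > 0) {
    hv <- build_histogram(rt$alpha_v, config$bin_width)
    nv <- try_fit(fit_normal_to_histogram(hv))
    al <- c(rt$alpha_l1, rt$alpha_l2, rt$alpha_l3)
    hl <- build_histogram(al, config$bin_width)
    sl <- try_fit(fit_skew_normal_to_histogram(hl))
    tl <- if (!is.null(sl)) try_fit(half_normal_approx(sl)) else NULL
    ha <- build_histogram(rt$anisotropy[is.finite(rt$anisotropy)], 0.1)
    sa <- try_fit(fit_skew_normal_to_histogram(ha))
    ta <- if (!is.null(sa)) try_fit(half_normal_approx(sa)) else NULL
    fits <- list(
      alpha_v = list(histogram = hv, normal = nv,
                     thresholds = if (!is.null(nv))
                       sigma_thresholds(nv, config$sigma_k) else NULL),
      alpha_l = list(histogram = hl, skew_normal = sl, two_half_normal = tl,
                     thresholds = if (!is.null(tl))
                       sigma_thresholds(tl, config$sigma_k) else NULL),
      anisotropy = list(histogram = ha, skew_normal = sa,
                        two_half_normal = ta))
  }

  nte_class <- if (nrow(rt) > 0) rt$nte_class else character(0)
  nte <- list(n_uniaxial = sum(nte_class == "uniaxial"),
              n_biaxial = sum(nte_class == "biaxial"),
              n_triaxial = sum(nte_class == "triaxial"),
              fraction_uniaxial = if (nrow(rt) > 0)
                mean(nte_class == "uniaxial") else NA_real_,
              fraction_biaxial = if (nrow(rt) > 0)
                mean(nte_class == "biaxial") else NA_real_)

  screen <- linearity_screen(built$families, config$r2_min, config)
  outliers <- if (nrow(rt) > 0 && !is.null(fits$alpha_v$thresholds)) {
    tabulate_outliers(rt, fits$alpha_v$thresholds,
                      min_points = config$outlier_min_points,
                      anisotropy_ref = config$anisotropy_ref,
                      r2_min = config$r2_min)
  } else NULL

  sizes <- vapply(built$families, function(f) f$n_entries, integer(1))
  structure(list(results = results, results_table = rt,
                 families = built$families, fits = fits, nte = nte,
                 screen = screen, outliers = outliers, log = log,
                 quarantined = built$quarantined,
                 family_size_spectrum = if (length(sizes) > 0) table(sizes)
                                        else table(integer(0)),
                 n_input_entries = n_input, config = config),
            class = "expansion_survey")
}

#' @export
print.expansion_survey <- function(x, ...) {
  cat(sprintf("expansion survey: %d input entries -> %d accepted families\n",
              x$n_input_entries, length(x$families)))
  if (length(x$families) > 0) {
    cat("  family sizes:",
        paste(sprintf("%s entries x%d", names(x$family_size_spectrum),
                      as.integer(x$family_size_spectrum)), collapse = ", "),
        "\n")
  }
  nv <- x$fits$alpha_v$normal
  if (!is.null(nv)) {
    cat(sprintf("  alpha_V normal fit: mean %.1f, sd %.1f p.p.m./K; 3-sigma (%.0f, %.0f)\n",
                nv$mean, nv$sd, x$fits$alpha_v$thresholds[["lower"]],
                x$fits$alpha_v$thresholds[["upper"]]))
  }
  tl <- x$fits$alpha_l$two_half_normal
  if (!is.null(tl)) {
    cat(sprintf("  alpha_L two-half-normal: centre %.1f, sd %.1f / %.1f p.p.m./K\n",
                tl$centre, tl$sd_lower, tl$sd_upper))
  }
  cat(sprintf("  NTE: %d uniaxial, %d biaxial of %d families\n",
              x$nte$n_uniaxial, x$nte$n_biaxial, nrow(x$results_table)))
  invisible(x)
}

#' Fit one family standalone
#'
#' Applies the full per-family expansion calculation to a bare
#' cell-versus-temperature table: the standalone entry point for a user with
#' one variable-temperature data set rather than a database extract. Cells
#' are Niggli-reduced first so the input setting does not matter.
#'
#' @param cells_vs_T A data.frame with columns
#'   `a, b, c, alpha, beta, gamma, temperature_K` (additional columns are
#'   ignored); at least two rows.
#' @param config A [survey_config()].
#' @return An `expansion_result` (see [fit_family_expansion()]), with the
#'   `two_point` flag set for two-row input.
#' @export
fit_single_family <- function(cells_vs_T, config = survey_config()) {
  need <- c("a", "b", "c", "alpha", "beta", "gamma", "temperature_K")
  if (!all(need %in% names(cells_vs_T))) {
    stop("cells_vs_T needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(cells_vs_T) < 2) stop("at least two determinations are required")
  e <- cells_vs_T
  e$refcode <- if ("refcode" %in% names(e)) e$refcode else
    sprintf("FAMILY%02d", seq_len(nrow(e)))
  e$r_factor <- if ("r_factor" %in% names(e)) e$r_factor else NA_real_
  e$publication_id <- if ("publication_id" %in% names(e)) e$publication_id
                      else "single"
  e <- reduce_entry_cells(e)
  if (!all(e$reduced)) stop("cell reduction failed for some rows")
  fam <- new_structure_family("family-1", e[order(e$temperature_K), ])
  fit_family_expansion(fam, config)
}

#' @export
print.expansion_result <- function(x, ...) {
  v <- x$volume; p <- x$principal
  su_txt <- function(val, su) {
    if (is.na(su)) sprintf("%.1f", val) else sprintf("%.1f (%.1f)", val, su)
  }
  cat(sprintf("expansion result for %s (%d points, %.0f-%.0f K%s)\n",
              x$family_id, x$n_points, v$t_min, v$t_max,
              if (x$two_point) ", two-point: no s.u.s" else ""))
  cat(sprintf("  alpha_V(298 K) = %s p.p.m./K  (R^2 = %s)\n",
              su_txt(v$alpha_v_298, v$su_alpha_v),
              if (is.na(v$r_squared)) "n/a" else sprintf("%.4f", v$r_squared)))
  for (k in 1:3) {
    cat(sprintf("  alpha_L%d(298 K) = %s p.p.m./K along (%+.3f, %+.3f, %+.3f)\n",
                k, su_txt(p$alpha_l[k], p$su_l[k]),
                p$axes[1, k], p$axes[2, k], p$axes[3, k]))
  }
  cat(sprintf("  anisotropy = %s; NTE class: %s\n",
              if (is.finite(x$anisotropy)) sprintf("%.3f", x$anisotropy)
              else "undefined", x$nte$nte_class))
  invisible(x)
}

#' Machine-readable survey summary
#'
#' @param survey An `expansion_survey`.
#' @return A plain list (JSON-ready): family counts and size spectrum, fitted
#'   distribution parameters, thresholds, NTE counts and the two-point
#'   fraction.
#' @export
survey_summary <- function(survey) {
  rt <- survey$results_table
  nv <- survey$fits$alpha_v$normal
  tl <- survey$fits$alpha_l$two_half_normal
  list(
    n_input_entries = survey$n_input_entries,
    n_families = length(survey$families),
    family_size_spectrum = as.list(survey$family_size_spectrum),
    fraction_two_point = if (nrow(rt) > 0) mean(rt$two_point) else NA_real_,
    alpha_v_normal = if (!is.null(nv)) nv[c("mean", "sd", "amplitude")] else NULL,
    alpha_v_thresholds = as.list(survey$fits$alpha_v$thresholds),
    alpha_l_two_half_normal = if (!is.null(tl))
      tl[c("centre", "sd_lower", "sd_upper")] else NULL,
    alpha_l_thresholds = as.list(survey$fits$alpha_l$thresholds),
    nte = survey$nte,
    n_screen_failed = length(survey$screen$failed)
  )
}

#' Write survey outputs to a directory
#'
#' @param survey An `expansion_survey`.
#' @param dir Output directory (created if needed): per-family results CSV,
#'   family assignments CSV, rejection log CSV, outlier CSVs and a JSON
#'   summary.
#' @return `dir`, invisibly.
#' @export
write_survey_outputs <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(survey$results_table,
                   file.path(dir, "family_results.csv"), row.names = FALSE)
  utils::write.csv(family_assignments(survey$families),
                   file.path(dir, "family_assignments.csv"), row.names = FALSE)
  utils::write.csv(survey$log, file.path(dir, "rejection_log.csv"),
                   row.names = FALSE)
  if (!is.null(survey$outliers)) {
    utils::write.csv(survey$outliers$high_alpha_v,
                     file.path(dir, "outliers_high_alpha_v.csv"),
                     row.names = FALSE)
    utils::write.csv(survey$outliers$low_alpha_v,
                     file.path(dir, "outliers_low_alpha_v.csv"),
                     row.names = FALSE)
    utils::write.csv(survey$outliers$extreme_anisotropy,
                     file.path(dir, "outliers_extreme_anisotropy.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(survey_summary(survey), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
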