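#' Configuration of the synthetic structure-database generator
#'
#' Defines the study conditions the generator emulates: a database of
#' refcode families containing redeterminations of the same phase at several
#' temperatures in the 90-300 K window, dominated by two-entry families
#' (about 85 percent, with a decreasing tail up to 14 entries), a volumetric
#' expansion population centred on 161 p.p.m. K\eqn{^{-1}} with standard
#' deviation 51, realistic uniaxial/biaxial NTE rates, small cell-parameter
#' measurement noise, and the documented error modes of database extracts:
#' wrongly reported temperatures, unflagged high-pressure determinations,
#' phase transitions, duplicate publications and alternative space-group
#' settings of one lattice.
#'
#' @param n_families Number of phase families to generate.
#' @param points_per_family Named probability vector over family sizes
#'   `2..14`.
#' @param temperature_window_K True temperatures are placed in this window,
#'   with every family topped by a room-temperature determination.
#' @param system_mix Probabilities of drawing a triclinic / monoclinic /
#'   orthorhombic reference cell.
#' @param alpha_v_mean,alpha_v_sd Normal population of the planted
#'   volumetric coefficient at 298 K, p.p.m. K\eqn{^{-1}}.
#' @param nte_uniaxial_rate,nte_biaxial_rate Probability that a family is
#'   planted with one / two negative principal coefficients.
#' @param cell_length_noise Relative standard deviation of the measurement
#'   noise on cell lengths.
#' @param cell_angle_noise_deg Standard deviation of the noise on cell
#'   angles, degrees.
#' @param missing_temperature_rate Probability that the room-temperature
#'   determination carries no recorded temperature (true value 293 K).
#' @param explicit_room_T_rate Probability that the room-temperature
#'   determination is recorded at an explicit value drawn in 283-303 K.
#' @param multi_publication_rate Probability that a family with 3 or more
#'   points mixes two publications.
#' @param error_rates Named vector of per-family injection probabilities for
#'   `wrong_temperature`, `high_pressure_unflagged`, `phase_transition`,
#'   `duplicate_publication`, `alternative_setting` (at most one mode per
#'   family; `wrong_temperature` and `phase_transition` are only drawn for
#'   families with four or more points; the sum must not exceed 1).
#' @param polymorph_rate Probability that a family shares its refcode root
#'   with an additional polymorph family with a distinct reduced cell.
#' @param nonconforming_rate Probability of appending an extra entry that
#'   violates one screening constraint (flagged pressure, missing
#'   coordinates, inorganic, polymeric).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_families = 1000,
                             points_per_family = default_family_size_probs(),
                             temperature_window_K = c(90, 300),
                             system_mix = c(triclinic = 0.25,
                                            monoclinic = 0.50,
                                            orthorhombic = 0.25),
                             alpha_v_mean = 161,
                             alpha_v_sd = 51,
                             nte_uniaxial_rate = 0.30,
                             nte_biaxial_rate = 0.03,
                             cell_length_noise = 2e-4,
                             cell_angle_noise_deg = 0.02,
                             missing_temperature_rate = 0.2,
                             explicit_room_T_rate = 0.3,
                             multi_publication_rate = 0.15,
                             error_rates = c(wrong_temperature = 0.02,
                                             high_pressure_unflagged = 0.02,
                                             phase_transition = 0.02,
                                             duplicate_publication = 0.02,
                                             alternative_setting = 0.02),
                             polymorph_rate = 0.05,
                             nonconforming_rate = 0.02) {
  modes <- c("wrong_temperature", "high_pressure_unflagged", "phase_transition",
             "duplicate_publication", "alternative_setting")
  er <- c(wrong_temperature = 0, high_pressure_unflagged = 0,
          phase_transition = 0, duplicate_publication = 0,
          alternative_setting = 0)
  er[names(error_rates)] <- error_rates
  if (!all(names(error_rates) %in% modes)) {
    stop("unknown error mode in error_rates")
  }
  cfg <- list(n_families = n_families,
              points_per_family = points_per_family / sum(points_per_family),
              temperature_window_K = temperature_window_K,
              system_mix = system_mix / sum(system_mix),
              alpha_v_mean = alpha_v_mean, alpha_v_sd = alpha_v_sd,
              nte_uniaxial_rate = nte_uniaxial_rate,
              nte_biaxial_rate = nte_biaxial_rate,
              cell_length_noise = cell_length_noise,
              cell_angle_noise_deg = cell_angle_noise_deg,
              missing_temperature_rate = missing_temperature_rate,
              explicit_room_T_rate = explicit_room_T_rate,
              multi_publication_rate = multi_publication_rate,
              error_rates = er, polymorph_rate = polymorph_rate,
              nonconforming_rate = nonconforming_rate)
  stopifnot(cfg$n_families > 0, all(cfg$error_rates >= 0),
            sum(cfg$error_rates) <= 1,
            all(cfg$points_per_family >= 0))
  class(cfg) <- "generator_config"
  cfg
}

#' Default family-size distribution
#'
#' About 85 percent two-entry families, 9 percent three-entry, 2.5 percent
#' four-entry and a geometrically decreasing tail up to 14 entries.
#'
#' @return Named probability vector over sizes `2..14`.
#' @export
default_family_size_probs <- function() {
  tail_sizes <- 5:14
  tail <- 0.5^(tail_sizes - 5)
  p <- c(0.845, 0.093, 0.025, 0.037 * tail / sum(tail))
  names(p) <- as.character(c(2, 3, 4, tail_sizes))
  p
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotation_about_y <- function(theta) {
  matrix(c(cos(theta), 0, sin(theta), 0, 1, 0, -sin(theta), 0, cos(theta)),
         3, 3)
}

# draw a near-reduced reference cell for a crystal system
draw_reference_cell <- function(system) {
  len <- sort(stats::runif(3, 5, 15))
  switch(system,
    orthorhombic = unit_cell(len[1], len[2], len[3], 90, 90, 90),
    monoclinic = unit_cell(len[1], len[2], len[3], 90,
                           stats::runif(1, 91, 99), 90),
    triclinic = unit_cell(len[1], len[2], len[3],
                          stats::runif(1, 91, 99), stats::runif(1, 91, 99),
                          stats::runif(1, 91, 99)))
}

# split a target alpha_V(298) into three planted alpha_L(298) values
split_alpha_targets <- function(alpha_v, nte_uni, nte_bi) {
  u <- stats::runif(1)
  lognormal_split <- function(total, n, sd) {
    x <- exp(stats::rnorm(n, 0, sd))
    total * x / sum(x)
  }
  if (u < nte_bi) {
    neg <- -abs(stats::rnorm(2, 15, 15)) - 1
    c(neg, alpha_v - sum(neg))
  } else if (u < nte_bi + nte_uni) {
    neg <- -abs(stats::rnorm(1, 25, 20)) - 1
    c(neg, lognormal_split(alpha_v - neg, 2, 0.35))
  } else {
    lognormal_split(alpha_v, 3, 0.45)
  }
}

# planted 298 K coefficient (p.p.m.) -> strain rate per K referenced to T_ref
rate_from_alpha298 <- function(alpha_ppm, t_ref) {
  a <- alpha_ppm * 1e-6
  a / (1 - a * (298 - t_ref))
}

# design true temperatures: lowest-T reference up to a room-T top point,
# spaced > 12 K so deduplication keeps every point
design_temperatures <- function(n, window, top = 293) {
  if (n == 2) return(c(stats::runif(1, window[1], top - 50), top))
  t_low <- stats::runif(1, window[1], min(180, top - 12 * (n - 1)))
  t <- seq(t_low, top, length.out = n)
  jitter <- stats::runif(n - 2, -3, 3)
  t[2:(n - 1)] <- t[2:(n - 1)] + jitter
  t
}

random_refcode_root <- function() {
  paste(sample(LETTERS, 6, replace = TRUE), collapse = "")
}

# the P2_1/c <-> P2_1/n style re-setting used for alternative_setting injections
alt_setting_matrix <- matrix(c(1, 0, 0, 0, 1, 0, -1, 0, 1), 3, 3)

#' Generate one synthetic structure family
#'
#' Draws a reference cell for a crystal system, plants a strain-rate tensor
#' respecting the system's symmetry constraints (the monoclinic twofold axis
#' keeps one principal axis on \strong{b}; orthorhombic axes are the cell
#' axes), evolves the cell across the designed temperatures by the exact
#' finite deformation \eqn{A(T) = (I + \dot e\,(T - T_{ref}))\,A_{ref}},
#' perturbs the resulting cell parameters with measurement noise and attaches
#' refcodes, publications and R-factors. At most one error mode is injected
#' per family, after the ground truth is recorded.
#'
#' @param config A [generator_config()].
#' @param root Refcode root to use (6 letters).
#' @param family_label Truth label for the family.
#' @param publication_seed Integer used to construct publication identifiers.
#' @return A list with `entries` (rows of the survey schema plus nothing
#'   else), `truth_family` (one-row data.frame: planted coefficients, rates,
#'   reference temperature, crystal system, injected error mode) and
#'   `truth_entries` (per-entry family label, true temperature, error role).
#' @export
generate_family <- function(config, root, family_label, publication_seed) {
  system <- sample(names(config$system_mix), 1, prob = config$system_mix)
  n <- as.integer(sample(names(config$points_per_family), 1,
                         prob = config$points_per_family))
  # room-temperature convention of the top point: unrecorded (assumed 293 K
  # downstream), explicitly recorded in the room range, or recorded at 293 K
  u_room <- stats::runif(1)
  if (u_room < config$missing_temperature_rate) {
    top_true <- 293; top_recorded <- NA_real_
  } else if (u_room < config$missing_temperature_rate +
               config$explicit_room_T_rate) {
    top_true <- round(stats::runif(1, 283, config$temperature_window_K[2]))
    top_recorded <- top_true
  } else {
    top_true <- 293; top_recorded <- 293
  }
  t_true <- design_temperatures(n, config$temperature_window_K, top_true)
  t_ref <- t_true[1]
  alpha_v <- stats::rnorm(1, config$alpha_v_mean, config$alpha_v_sd)
  alpha_l <- sort(split_alpha_targets(alpha_v, config$nte_uniaxial_rate,
                                      config$nte_biaxial_rate))
  rates <- vapply(alpha_l, rate_from_alpha298, numeric(1), t_ref = t_ref)
  perm <- sample(1:3)
  Edot <- switch(system,
    # principal axes on the cell axes
    orthorhombic = diag(rates[perm]),
    # one eigenvector pinned to the unique axis (y in the default frame),
    # the other two rotated freely in the perpendicular xz-plane
    monoclinic = {
      Rxz <- rotation_about_y(stats::runif(1, 0, pi))
      E <- Rxz %*% diag(c(rates[perm][1], 0, rates[perm][3])) %*% t(Rxz)
      E[2, 2] <- rates[perm][2]
      E
    },
    # no symmetry constraint: a uniformly random orientation
    triclinic = {
      Q <- random_rotation()
      Q %*% diag(rates) %*% t(Q)
    })

  ref_cell <- draw_reference_cell(system)
  A_ref <- orthogonalization_matrix(ref_cell)
  # error modes that corrupt a linear fit are only meaningful on families
  # with enough points to diagnose them; draw among eligible modes
  er <- config$error_rates
  if (n < 4) er[c("wrong_temperature", "phase_transition")] <- 0
  error_mode <- draw_error_mode(er)

  pub_main <- sprintf("PUB%05d", publication_seed)
  pub_alt <- sprintf("PUB%05dB", publication_seed)
  multi_pub <- n >= 3 && stats::runif(1) < config$multi_publication_rate

  pressure_row <- if (error_mode == "high_pressure_unflagged") n else 0L
  pressure_shrink <- if (pressure_row > 0) stats::runif(1, 0.03, 0.10) else 0
  transition_T <- Inf
  transition_jump <- 0
  if (error_mode == "phase_transition") {
    transition_T <- stats::runif(1, t_true[2], t_true[n - 1] + 1e-9)
    transition_jump <- stats::runif(1, 0.02, 0.04)
  }

  rows <- vector("list", n)
  roles <- rep("none", n)
  for (i in seq_len(n)) {
    e <- Edot * (t_true[i] - t_ref)
    A_t <- (diag(3) + e) %*% A_ref
    scale <- 1
    if (i == pressure_row) {
      scale <- scale * (1 - pressure_shrink)^(1 / 3)
      roles[i] <- "high_pressure_unflagged"
    }
    if (error_mode == "phase_transition" && t_true[i] > transition_T) {
      scale <- scale * (1 + transition_jump)^(1 / 3)
      if (roles[i] == "none") roles[i] <- "phase_transition"
    }
    cell_t <- cell_from_metric(crossprod(A_t * scale))
    pars <- as.numeric(cell_t)
    pars[1:3] <- pars[1:3] *
      (1 + stats::rnorm(3, 0, config$cell_length_noise))
    pars[4:6] <- pars[4:6] + stats::rnorm(3, 0, config$cell_angle_noise_deg)
    rows[[i]] <- pars
  }

  # one entry re-expressed in an alternative space-group setting
  if (error_mode == "alternative_setting") {
    i <- sample(seq_len(n), 1)
    G <- metric_tensor(unit_cell(rows[[i]][1], rows[[i]][2], rows[[i]][3],
                                 rows[[i]][4], rows[[i]][5], rows[[i]][6]))
    Gp <- t(alt_setting_matrix) %*% G %*% alt_setting_matrix
    rows[[i]] <- as.numeric(cell_from_metric(Gp))
    roles[i] <- "alternative_setting"
  }

  t_recorded <- t_true
  t_recorded[n] <- top_recorded
  if (error_mode == "wrong_temperature") {
    # a warm structure archived with a (much too low) analysis temperature;
    # keep the bogus value clear of the other determinations so it survives
    # deduplication and corrupts the linear fit
    i <- n - 1L
    bogus <- max(config$temperature_window_K[1], t_true[i] - 100)
    others <- t_true[-i]
    while (any(abs(bogus - others) < 12) &&
           bogus > config$temperature_window_K[1]) {
      bogus <- max(config$temperature_window_K[1], bogus - 12)
    }
    t_recorded[i] <- bogus
    roles[i] <- "wrong_temperature"
  }

  pubs <- rep(pub_main, n)
  if (multi_pub) pubs[1] <- pub_alt

  entries <- data.frame(
    refcode = sprintf("%s%02d", root, seq_len(n)),
    a = vapply(rows, `[`, numeric(1), 1),
    b = vapply(rows, `[`, numeric(1), 2),
    c = vapply(rows, `[`, numeric(1), 3),
    alpha = vapply(rows, `[`, numeric(1), 4),
    beta = vapply(rows, `[`, numeric(1), 5),
    gamma = vapply(rows, `[`, numeric(1), 6),
    temperature_K = t_recorded,
    r_factor = round(stats::runif(n, 0.02, 0.08), 4),
    pressure_flag = FALSE,
    has_coords = TRUE, organic = TRUE, polymeric = FALSE,
    publication_id = pubs, stringsAsFactors = FALSE)

  if (error_mode == "duplicate_publication") {
    # the same determination published twice: same cell within noise, a
    # different publication and R-factor, a nearby temperature
    i <- sample(seq_len(n), 1)
    dup <- entries[i, , drop = FALSE]
    dup$refcode <- sprintf("%s%02d", root, n + 1L)
    dup$a <- dup$a * (1 + stats::rnorm(1, 0, config$cell_length_noise))
    dup$r_factor <- round(min(0.2, dup$r_factor + stats::runif(1, 0.005, 0.02)), 4)
    dup$publication_id <- pub_alt
    if (!is.na(dup$temperature_K)) {
      dup$temperature_K <- dup$temperature_K + stats::runif(1, 0, 5)
    }
    entries <- rbind(entries, dup)
    roles <- c(roles, "duplicate_publication")
    t_true <- c(t_true, t_true[i])
  }

  truth_family <- data.frame(
    family_label = family_label, refcode_root = root,
    crystal_system = system, n_points = n, t_ref = t_ref,
    t_max = max(t_true, na.rm = TRUE),
    alpha_v_298 = alpha_v,
    alpha_l1_298 = alpha_l[1], alpha_l2_298 = alpha_l[2],
    alpha_l3_298 = alpha_l[3],
    rate1 = rates[1], rate2 = rates[2], rate3 = rates[3],
    error_mode = error_mode, single_publication = !multi_pub,
    stringsAsFactors = FALSE)
  truth_entries <- data.frame(
    refcode = entries$refcode, family_label = family_label,
    true_temperature_K = t_true, error_role = roles,
    stringsAsFactors = FALSE)
  list(entries = entries, truth_family = truth_family,
       truth_entries = truth_entries)
}

draw_error_mode <- function(rates) {
  u <- stats::runif(1)
  cum <- cumsum(rates)
  hit <- which(u < cum)
  if (length(hit) == 0) "none" else names(rates)[hit[1]]
}

#' Generate a synthetic survey
#'
#' Emits a complete entry table in the survey CSV schema together with a
#' parallel ground-truth table: planted expansion coefficients per family and
#' per-entry family labels and injected-error roles. Deterministic for a
#' fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list: `entries`, `truth_families`, `truth_entries`.
#' @export
generate_survey <- function(config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roots <- character(0)
  entries <- list(); truth_f <- list(); truth_e <- list()
  k <- 0L
  for (i in seq_len(config$n_families)) {
    repeat {
      root <- random_refcode_root()
      if (!root %in% roots) break
    }
    roots <- c(roots, root)
    k <- k + 1L
    fam <- generate_family(config, root, sprintf("%s-p1", root), k)
    entries[[length(entries) + 1L]] <- fam$entries
    truth_f[[length(truth_f) + 1L]] <- fam$truth_family
    truth_e[[length(truth_e) + 1L]] <- fam$truth_entries
    if (stats::runif(1) < config$polymorph_rate) {
      # a polymorph: same refcode root, distinct lattice, its own family
      k <- k + 1L
      poly <- generate_family(config, root, sprintf("%s-p2", root), k)
      m <- nrow(fam$entries)
      poly$entries$refcode <- sprintf("%s%02d", root,
                                      m + seq_len(nrow(poly$entries)))
      poly$truth_entries$refcode <- poly$entries$refcode
      entries[[length(entries) + 1L]] <- poly$entries
      truth_f[[length(truth_f) + 1L]] <- poly$truth_family
      truth_e[[length(truth_e) + 1L]] <- poly$truth_entries
    }
  }
  entries <- do.call(rbind, entries)
  truth_entries <- do.call(rbind, truth_e)
  # extra nonconforming entries exercising the screening constraints
  n_bad <- stats::rbinom(1, nrow(entries), config$nonconforming_rate)
  if (n_bad > 0) {
    idx <- sample(seq_len(nrow(entries)), n_bad, replace = FALSE)
    bad <- entries[idx, , drop = FALSE]
    bad$refcode <- sprintf("%s9%d", substr(bad$refcode, 1, 6),
                           seq_len(n_bad) %% 10)
    kind <- sample(c("pressure", "no_coords", "not_organic", "polymeric"),
                   n_bad, replace = TRUE)
    bad$pressure_flag <- kind == "pressure"
    bad$has_coords <- kind != "no_coords"
    bad$organic <- kind != "not_organic"
    bad$polymeric <- kind == "polymeric"
    entries <- rbind(entries, bad)
    truth_entries <- rbind(truth_entries,
                           data.frame(refcode = bad$refcode,
                                      family_label = "nonconforming",
                                      true_temperature_K = NA_real_,
                                      error_role = "nonconforming",
                                      stringsAsFactors = FALSE))
  }
  rownames(entries) <- NULL
  list(entries = entries,
       truth_families = do.call(rbind, truth_f),
       truth_entries = truth_entries)
}

#' Write a synthetic survey to disk
#'
#' @param survey A [generate_survey()] result.
#' @param dir Output directory; writes `entries.csv`, `truth_families.csv`
#'   and `truth_entries.csv`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(survey$entries, file.path(dir, "entries.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(survey$truth_families, file.path(dir, "truth_families.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$truth_entries, file.path(dir, "truth_entries.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Recall of planted error modes
#'
#' Measures how often each injected error mode is caught by the survey's
#' screening and outlier logic: a wrongly reported temperature or a planted
#' phase transition counts as caught when its family fails the R-squared
#' linearity screen; an unflagged high-pressure determination counts as
#' caught when its family either fails the screen or falls at or below the
#' lower volumetric threshold (two-point families there are flagged
#' suspect).
#'
#' @param survey An `expansion_survey` run on synthetic entries.
#' @param truth The matching [generate_survey()] truth tables.
#' @return A data.frame with one row per injected mode: `n_injected`,
#'   `n_caught`, `recall`.
#' @export
error_recall <- function(survey, truth) {
  tf <- truth$truth_families
  # map each truth family to the recovered family id via its member refcodes
  assign <- family_assignments(survey$families)
  te <- truth$truth_entries
  fam_of_label <- function(label) {
    refs <- te$refcode[te$family_label == label]
    ids <- unique(assign$family_id[assign$refcode %in% refs])
    if (length(ids) == 0) NA_character_ else ids[1]
  }
  failed_ids <- vapply(survey$screen$failed, function(f) f$family$family_id,
                       character(1))
  rt <- survey$results_table
  lower <- survey$fits$alpha_v$thresholds[["lower"]]
  caught <- function(label, mode) {
    fid <- fam_of_label(label)
    if (is.na(fid)) return(FALSE)
    screen_fail <- fid %in% failed_ids
    below <- if (!is.null(lower) && fid %in% rt$family_id) {
      rt$alpha_v[rt$family_id == fid] <= lower
    } else FALSE
    switch(mode,
           wrong_temperature = screen_fail,
           phase_transition = screen_fail,
           high_pressure_unflagged = screen_fail || below,
           FALSE)
  }
  modes <- c("wrong_temperature", "high_pressure_unflagged", "phase_transition")
  rows <- lapply(modes, function(mode) {
    labels <- tf$family_label[tf$error_mode == mode]
    n_caught <- sum(vapply(labels, caught, logical(1), mode = mode))
    data.frame(error_mode = mode, n_injected = length(labels),
               n_caught = n_caught,
               recall = if (length(labels) > 0) n_caught / length(labels)
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
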