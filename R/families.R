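new_structure_family <- function(family_id, entries) {
  structure(list(
    family_id = family_id,
    entries = entries,
    n_entries = nrow(entries),
    single_publication = length(unique(entries$publication_id)) == 1L
  ), class = "structure_family")
}

#' @export
print.structure_family <- function(x, ...) {
  cat(sprintf("structure family %s: %d entries, %s publication(s), T = %s K\n",
              x$family_id, x$n_entries,
              if (x$single_publication) "single" else "multiple",
              paste(round(x$entries$temperature_K), collapse = ", ")))
  invisible(x)
}

# Niggli-reduce the cells of an entry table; returns the table with red_*
# columns appended and a logical `reduced` marking successes. Failures are
# quarantined (kept, flagged, warned about) rather than silently dropped so
# that data errors remain auditable.
reduce_entry_cells <- function(entries) {
  n <- nrow(entries)
  red <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("red_a", "red_b", "red_c",
                                        "red_alpha", "red_beta", "red_gamma")))
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      niggli_reduce(as.numeric(entries[i, c("a", "b", "c", "alpha", "beta", "gamma")])),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("cell reduction failed for ", entries$refcode[i], ": ",
              conditionMessage(res), " (entry quarantined)", call. = FALSE)
    } else {
      red[i, ] <- as.numeric(res$cell)
      ok[i] <- TRUE
    }
  }
  cbind(entries, as.data.frame(red), reduced = ok)
}

#' Partition one refcode family into structure families
#'
#' Entries sharing a refcode root may be redeterminations of one phase at
#' different temperatures, polymorphs, or the same lattice published in a
#' different space-group setting. The partition works purely on the lattice
#' metric: cells are Niggli-reduced and clustered by greedy single linkage on
#' the metric deformation measure, so alternative settings of one lattice
#' coincide while polymorphs with genuinely different reduced cells separate.
#'
#' @param entries Entry table whose rows all share one 6-letter refcode root.
#'   Processing order (and hence cluster numbering) is fixed by sorting on
#'   refcode then temperature.
#' @param tol Deformation-measure acceptance threshold; chains of pairwise
#'   measures below `tol` define a family.
#' @return A list with `families` (list of `structure_family`, entries carrying
#'   the reduced cell in `red_*` columns) and `quarantined` (rows whose cell
#'   failed to reduce).
#' @export
partition_refcode_family <- function(entries, tol = 0.12) {
  root <- unique(refcode_root(entries$refcode))
  if (length(root) != 1) {
    stop("partition_refcode_family expects entries from a single refcode root")
  }
  ord <- order(entries$refcode, entries$temperature_K)
  entries <- entries[ord, , drop = FALSE]
  entries <- reduce_entry_cells(entries)
  quarantined <- entries[!entries$reduced, , drop = FALSE]
  entries <- entries[entries$reduced, , drop = FALSE]
  clusters <- list() # each: integer row indices into `entries`
  red_cells <- lapply(seq_len(nrow(entries)), function(i) {
    as.numeric(entries[i, c("red_a", "red_b", "red_c",
                            "red_alpha", "red_beta", "red_gamma")])
  })
  for (i in seq_len(nrow(entries))) {
    linked <- which(vapply(clusters, function(members) {
      any(vapply(members, function(j) {
        deformation_measure(red_cells[[j]], red_cells[[i]], check = FALSE) <= tol
      }, logical(1)))
    }, logical(1)))
    if (length(linked) == 0) {
      clusters[[length(clusters) + 1L]] <- i
    } else {
      # single linkage: the new entry may bridge several clusters; merge them
      merged <- c(unlist(clusters[linked]), i)
      clusters <- clusters[-linked]
      clusters[[length(clusters) + 1L]] <- sort(merged)
    }
  }
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  families <- lapply(seq_along(clusters), function(k) {
    new_structure_family(sprintf("%s-%d", root, k),
                         entries[clusters[[k]], , drop = FALSE])
  })
  list(families = families, quarantined = quarantined)
}

#' Deduplicate a family by temperature
#'
#' Keeps one representative determination at each unique temperature. Entries
#' are sorted by temperature and grouped greedily from the bottom: an entry
#' joins the current group when it lies within `tol_T` of the group's anchor
#' (its first, lowest-temperature member), otherwise it starts a new group.
#' Within each group the entry with the lowest crystallographic R-factor is
#' retained; a reported R-factor beats a missing one, and remaining ties go to
#' the alphabetically earliest refcode.
#'
#' @param family A `structure_family` with temperatures assigned.
#' @param tol_T Grouping tolerance in kelvin.
#' @return The deduplicated `structure_family`, temperatures strictly
#'   increasing.
#' @export
deduplicate_by_temperature <- function(family, tol_T = 10) {
  e <- family$entries
  if (anyNA(e$temperature_K)) {
    stop("deduplicate_by_temperature requires assigned temperatures")
  }
  e <- e[order(e$temperature_K, e$refcode), , drop = FALSE]
  group <- integer(nrow(e))
  anchor <- -Inf; g <- 0L
  for (i in seq_len(nrow(e))) {
    if (e$temperature_K[i] - anchor > tol_T) {
      g <- g + 1L
      anchor <- e$temperature_K[i]
    }
    group[i] <- g
  }
  keep <- vapply(split(seq_len(nrow(e)), group), function(idx) {
    r <- e$r_factor[idx]
    r[is.na(r)] <- Inf
    idx[order(r, e$refcode[idx])[1]]
  }, integer(1))
  new_structure_family(family$family_id, e[sort(keep), , drop = FALSE])
}

#' Apply the temperature-window filters to a family
#'
#' Restricts a deduplicated family to the survey's 90-300 K window and
#' rejects families that cannot support a meaningful expansion estimate: the
#' family must retain a determination at or above `min_top_K`, span at least
#' `min_range_K`, and keep at least two entries.
#'
#' @param family A deduplicated `structure_family`.
#' @param window_K Two-element inclusive temperature window in kelvin.
#' @param min_top_K Required maximum temperature.
#' @param min_range_K Required total temperature range.
#' @return The filtered `structure_family`, or an object of class
#'   `family_rejection` carrying a `reason` code (`too_few_entries`,
#'   `no_273K`, `range_lt_50K`).
#' @export
filter_family <- function(family, window_K = c(90, 300), min_top_K = 273,
                          min_range_K = 50) {
  e <- family$entries
  e <- e[e$temperature_K >= window_K[1] & e$temperature_K <= window_K[2], ,
         drop = FALSE]
  reject <- function(reason) {
    structure(list(family_id = family$family_id, reason = reason),
              class = "family_rejection")
  }
  if (nrow(e) < 2) return(reject("too_few_entries"))
  if (max(e$temperature_K) < min_top_K) return(reject("no_273K"))
  if (diff(range(e$temperature_K)) < min_range_K) return(reject("range_lt_50K"))
  new_structure_family(family$family_id, e)
}

#' Single-publication subset
#'
#' The reliable test subset of the survey: families whose determinations all
#' come from one publication (measured on one instrument, usually one
#' crystal) and that contain at least `min_n` temperature points.
#'
#' @param families List of `structure_family`.
#' @param min_n Minimum number of entries.
#' @return The qualifying sub-list.
#' @export
single_publication_subset <- function(families, min_n = 4) {
  Filter(function(f) f$single_publication && f$n_entries >= min_n, families)
}

#' Build structure families from a raw entry table
#'
#' Runs the full curation sequence: constraint screening, room-temperature
#' assignment, refcode-root grouping, reduced-cell partitioning, temperature
#' deduplication and the temperature-window filters.
#'
#' @param entries A validated entry table ([read_entries_csv()] schema).
#' @param config A [survey_config()].
#' @return A list with `families` (accepted `structure_family` objects),
#'   `log` (data.frame of every discarded entry or family with a
#'   machine-readable reason code) and `quarantined` (entries whose cell
#'   failed Niggli reduction).
#' @export
build_families <- function(entries, config = survey_config()) {
  entries <- validate_entries(entries)
  scr <- screen_entries(entries)
  log <- data.frame(id = scr$rejected$refcode,
                    stage = rep("screen", nrow(scr$rejected)),
                    reason = scr$rejected$reason,
                    n_entries = rep(1L, nrow(scr$rejected)),
                    stringsAsFactors = FALSE)
  kept <- assign_temperature(scr$kept, config$room_temperature_K)
  families <- list(); quarantined <- list()
  for (root in sort(unique(refcode_root(kept$refcode)))) {
    part <- partition_refcode_family(kept[refcode_root(kept$refcode) == root, ,
                                          drop = FALSE],
                                     tol = config$deformation_tol)
    if (nrow(part$quarantined) > 0) {
      quarantined[[length(quarantined) + 1L]] <- part$quarantined
      log <- rbind(log, data.frame(id = part$quarantined$refcode,
                                   stage = "reduce", reason = "unreducible_cell",
                                   n_entries = 1L, stringsAsFactors = FALSE))
    }
    families <- c(families, part$families)
  }
  accepted <- list()
  for (fam in families) {
    if (fam$n_entries < 2) {
      log <- rbind(log, data.frame(id = fam$family_id, stage = "partition",
                                   reason = "singleton_family",
                                   n_entries = fam$n_entries,
                                   stringsAsFactors = FALSE))
      next
    }
    n_before <- fam$n_entries
    fam <- deduplicate_by_temperature(fam, config$dedup_tol_K)
    if (fam$n_entries < n_before) {
      log <- rbind(log, data.frame(id = fam$family_id, stage = "dedup",
                                   reason = "duplicate_temperature",
                                   n_entries = n_before - fam$n_entries,
                                   stringsAsFactors = FALSE))
    }
    filt <- filter_family(fam, config$temperature_window_K,
                          config$min_top_K, config$min_range_K)
    if (inherits(filt, "family_rejection")) {
      log <- rbind(log, data.frame(id = fam$family_id, stage = "filter",
                                   reason = filt$reason,
                                   n_entries = fam$n_entries,
                                   stringsAsFactors = FALSE))
    } else {
      if (filt$n_entries < fam$n_entries) {
        log <- rbind(log, data.frame(id = fam$family_id, stage = "filter",
                                     reason = "outside_window",
                                     n_entries = fam$n_entries - filt$n_entries,
                                     stringsAsFactors = FALSE))
      }
      accepted[[length(accepted) + 1L]] <- filt
    }
  }
  list(families = accepted, log = log,
       quarantined = if (length(quarantined) > 0) do.call(rbind, quarantined)
                     else NULL)
}

#' Family assignment table
#'
#' Flattens a list of structure families into the assignment CSV schema
#' (`family_id, refcode, temperature_K, kept`).
#'
#' @param families List of `structure_family`.
#' @return A data.frame, one row per kept entry.
#' @export
family_assignments <- function(families) {
  if (length(families) == 0) {
    return(data.frame(family_id = character(0), refcode = character(0),
                      temperature_K = numeric(0), kept = logical(0)))
  }
  do.call(rbind, lapply(families, function(f) {
    data.frame(family_id = f$family_id, refcode = f$entries$refcode,
               temperature_K = f$entries$temperature_K, kept = TRUE,
               stringsAsFactors = FALSE)
  }))
}
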