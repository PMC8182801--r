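cubic <- unit_cell(10, 10, 10, 90, 90, 90)

test_that("screening removes exactly the constraint violators, preserving order", {
  rows <- rbind(
    make_entry("AAAAAA01", cubic, 100),
    make_entry("AAAAAA02", cubic, 150, pressure_flag = TRUE),
    make_entry("AAAAAA03", cubic, 200),
    make_entry("AAAAAA04", cubic, 220, has_coords = FALSE),
    make_entry("AAAAAA05", cubic, 240, organic = FALSE),
    make_entry("AAAAAA06", cubic, 250),
    make_entry("AAAAAA07", cubic, 260, polymeric = TRUE),
    make_entry("AAAAAA08", cubic, 270),
    make_entry("AAAAAA09", cubic, 280),
    make_entry("AAAAAA10", cubic, 290))
  scr <- screen_entries(validate_entries(rows))
  expect_equal(nrow(scr$kept), 6)
  expect_equal(scr$kept$refcode,
               paste0("AAAAAA", c("01", "03", "06", "08", "09", "10")))
  # compliant list passes unchanged
  ok <- validate_entries(rbind(make_entry("BBBBBB01", cubic, 100),
                               make_entry("BBBBBB02", cubic, 293)))
  scr2 <- screen_entries(ok)
  expect_equal(scr2$kept, ok)
  expect_equal(nrow(scr2$rejected), 0)
  expect_setequal(scr$rejected$reason,
                  c("pressure", "no_coords", "not_organic", "polymeric"))
})

test_that("missing temperatures become 293 K and explicit values pass through", {
  expect_equal(assign_temperature(NA_real_), 293)
  expect_equal(assign_temperature(100), 100)
  expect_equal(assign_temperature(296), 296) # explicit room-range value kept
  tab <- rbind(make_entry("CCCCCC01", cubic, NA_real_),
               make_entry("CCCCCC02", cubic, 120))
  out <- assign_temperature(validate_entries(tab))
  expect_equal(out$temperature_K, c(293, 120))
})

test_that("partitioning joins identical cells and alternative settings, splits polymorphs", {
  mono <- unit_cell(5.2, 9.3, 11.1, 90, 101.5, 90)
  # P2_1/c vs P2_1/n: same lattice under the (1 0 0 / 0 1 0 / -1 0 1) re-basing
  M <- matrix(c(1, 0, 0, 0, 1, 0, -1, 0, 1), 3, 3)
  alt <- transform_cell(mono, M)
  tab <- validate_entries(rbind(make_entry("DDDDDD01", mono, 100),
                                make_entry("DDDDDD02", alt, 293)))
  part <- partition_refcode_family(tab)
  expect_length(part$families, 1)
  expect_equal(part$families[[1]]$n_entries, 2)

  # polymorph pair planted well beyond the tolerance
  poly <- unit_cell(5.2 * 1.35, 9.3, 11.1 / 1.25, 90, 113, 90)
  tab2 <- validate_entries(rbind(make_entry("EEEEEE01", mono, 100),
                                 make_entry("EEEEEE02", poly, 293)))
  r1 <- niggli_reduce(mono)$cell; r2 <- niggli_reduce(poly)$cell
  expect_gt(deformation_measure(r1, r2), 0.12)
  part2 <- partition_refcode_family(tab2)
  expect_length(part2$families, 2)

  expect_error(partition_refcode_family(
    validate_entries(rbind(make_entry("FFFFFF01", cubic, 100),
                           make_entry("GGGGGG01", cubic, 100)))),
    "single refcode root")
})

test_that("temperature deduplication keeps the lowest-R representative per group", {
  fam <- partition_refcode_family(validate_entries(rbind(
    make_entry("HHHHHH01", cubic, 100, r_factor = 0.05),
    make_entry("HHHHHH02", cubic, 105, r_factor = 0.03))))$families[[1]]
  dd <- deduplicate_by_temperature(fam)
  expect_equal(dd$n_entries, 1)
  expect_equal(dd$entries$refcode, "HHHHHH02")

  fam2 <- partition_refcode_family(validate_entries(rbind(
    make_entry("IIIIII01", cubic, 100),
    make_entry("IIIIII02", cubic, 150))))$families[[1]]
  expect_equal(deduplicate_by_temperature(fam2)$n_entries, 2)

  # greedy grouping anchored on the sorted list: {90, 99} then {108}
  fam3 <- partition_refcode_family(validate_entries(rbind(
    make_entry("JJJJJJ01", cubic, 90, r_factor = 0.04),
    make_entry("JJJJJJ02", cubic, 99, r_factor = 0.02),
    make_entry("JJJJJJ03", cubic, 108, r_factor = 0.06))))$families[[1]]
  dd3 <- deduplicate_by_temperature(fam3)
  expect_equal(dd3$entries$temperature_K, c(99, 108))

  # a reported R beats a missing one
  fam4 <- partition_refcode_family(validate_entries(rbind(
    make_entry("KKKKKK01", cubic, 100, r_factor = NA_real_),
    make_entry("KKKKKK02", cubic, 102, r_factor = 0.08))))$families[[1]]
  expect_equal(deduplicate_by_temperature(fam4)$entries$refcode, "KKKKKK02")
})

test_that("temperature-window filters enforce the 273 K and 50 K rules", {
  fam_ok <- partition_refcode_family(validate_entries(rbind(
    make_entry("LLLLLL01", cubic, 100), make_entry("LLLLLL02", cubic, 293)
  )))$families[[1]]
  expect_s3_class(filter_family(fam_ok), "structure_family")

  fam_range <- partition_refcode_family(validate_entries(rbind(
    make_entry("MMMMMM01", cubic, 250), make_entry("MMMMMM02", cubic, 293)
  )))$families[[1]]
  rej <- filter_family(fam_range)
  expect_s3_class(rej, "family_rejection")
  expect_equal(rej$reason, "range_lt_50K")

  fam_cold <- partition_refcode_family(validate_entries(rbind(
    make_entry("NNNNNN01", cubic, 90), make_entry("NNNNNN02", cubic, 120),
    make_entry("NNNNNN03", cubic, 150))))$families[[1]]
  rej2 <- filter_family(fam_cold)
  expect_s3_class(rej2, "family_rejection")
  expect_equal(rej2$reason, "no_273K")

  # entries outside 90-300 K are removed before the rules apply
  fam_wide <- partition_refcode_family(validate_entries(rbind(
    make_entry("OOOOOO01", cubic, 80), make_entry("OOOOOO02", cubic, 120),
    make_entry("OOOOOO03", cubic, 293), make_entry("OOOOOO04", cubic, 320)
  )))$families[[1]]
  kept <- filter_family(fam_wide)
  expect_equal(kept$n_entries, 2)
  expect_equal(kept$entries$temperature_K, c(120, 293))
})

test_that("single-publication subset applies both the publication and size rules", {
  mk <- function(root, n, pubs) {
    partition_refcode_family(validate_entries(do.call(rbind, lapply(
      seq_len(n), function(i) {
        make_entry(sprintf("%s%02d", root, i), cubic, 80 + 50 * i,
                   publication_id = pubs[(i - 1) %% length(pubs) + 1])
      }))))$families[[1]]
  }
  fams <- list(mk("PPPPPP", 4, "PUBX"),       # qualifies
               mk("QQQQQQ", 4, c("PUBX", "PUBY")), # two publications
               mk("RRRRRR", 3, "PUBX"))       # too few entries
  out <- single_publication_subset(fams, min_n = 4)
  expect_length(out, 1)
  expect_equal(out[[1]]$family_id, "PPPPPP-1")
})

test_that("family recovery on labelled synthetic data is near-perfect", {
  syn <- generate_survey(generator_config(n_families = 120), seed = 77)
  sv <- run_survey(syn$entries)
  assign <- family_assignments(sv$families)
  m <- merge(assign, syn$truth_entries, by = "refcode")
  # every kept entry appears exactly once
  expect_equal(anyDuplicated(assign$refcode), 0)
  expect_gte(rand_index(m$family_id, m$family_label), 0.95)
})
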