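test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_families = 25)
  s1 <- generate_survey(cfg, seed = 9)
  s2 <- generate_survey(cfg, seed = 9)
  expect_identical(s1, s2)
  s3 <- generate_survey(cfg, seed = 10)
  expect_false(identical(s1$entries, s3$entries))
})

test_that("the truth table covers every emitted entry exactly once", {
  syn <- generate_survey(generator_config(n_families = 40), seed = 21)
  expect_setequal(syn$entries$refcode, syn$truth_entries$refcode)
  expect_equal(anyDuplicated(syn$truth_entries$refcode), 0)
  # every planted family label appears in the truth-family table
  core <- unique(syn$truth_entries$family_label)
  core <- setdiff(core, "nonconforming")
  expect_setequal(core, syn$truth_families$family_label)
})

test_that("a noise-free family round-trips its planted coefficients almost exactly", {
  cfg <- generator_config(n_families = 1, cell_length_noise = 0,
                          cell_angle_noise_deg = 0, nonconforming_rate = 0,
                          polymorph_rate = 0, missing_temperature_rate = 0,
                          explicit_room_T_rate = 0, multi_publication_rate = 0,
                          error_rates = c(wrong_temperature = 0),
                          points_per_family = c(`5` = 1),
                          system_mix = c(orthorhombic = 1))
  set.seed(31)
  fam <- generate_family(cfg, "ZZZZZZ", "ZZZZZZ-p1", 1)
  res <- fit_single_family(fam$entries)
  planted <- unlist(fam$truth_family[c("alpha_l1_298", "alpha_l2_298",
                                       "alpha_l3_298")])
  expect_equal(res$principal$alpha_l, unname(planted), tolerance = 1e-3)
  expect_equal(res$volume$alpha_v_298, fam$truth_family$alpha_v_298,
               tolerance = 0.01)
})

test_that("zero injections yield a survey where every family passes the screen", {
  cfg <- generator_config(n_families = 60, nonconforming_rate = 0,
                          polymorph_rate = 0,
                          error_rates = c(wrong_temperature = 0))
  syn <- generate_survey(cfg, seed = 13)
  sv <- run_survey(syn$entries)
  expect_length(sv$screen$failed, 0)
  r2 <- sv$results_table$r2_v
  expect_true(all(r2[!is.na(r2)] > 0.99))
  expect_equal(length(sv$families), nrow(syn$truth_families))
})

test_that("planted error modes behave as designed", {
  # an alternative-setting entry still joins its family after reduction
  cfg_alt <- generator_config(n_families = 12, polymorph_rate = 0,
                              nonconforming_rate = 0,
                              points_per_family = c(`3` = 1),
                              error_rates = c(alternative_setting = 1))
  syn_alt <- generate_survey(cfg_alt, seed = 14)
  sv_alt <- run_survey(syn_alt$entries)
  expect_equal(length(sv_alt$families), 12)
  expect_true(all(vapply(sv_alt$families, function(f) f$n_entries,
                         integer(1)) == 3L))

  # a wrongly reported temperature makes its family fail the R^2 screen
  cfg_wt <- generator_config(n_families = 12, polymorph_rate = 0,
                             nonconforming_rate = 0,
                             points_per_family = c(`5` = 1),
                             error_rates = c(wrong_temperature = 1))
  syn_wt <- generate_survey(cfg_wt, seed = 15)
  sv_wt <- run_survey(syn_wt$entries)
  rec <- error_recall(sv_wt, syn_wt)
  wt <- rec[rec$error_mode == "wrong_temperature", ]
  expect_equal(wt$n_injected, 12)
  expect_gte(wt$recall, 0.9)

  # duplicate publications are collapsed by lowest-R retention
  cfg_dup <- generator_config(n_families = 10, polymorph_rate = 0,
                              nonconforming_rate = 0,
                              points_per_family = c(`3` = 1),
                              error_rates = c(duplicate_publication = 1))
  syn_dup <- generate_survey(cfg_dup, seed = 16)
  expect_equal(nrow(syn_dup$entries), 40) # 3 + 1 duplicate per family
  sv_dup <- run_survey(syn_dup$entries)
  expect_true(all(vapply(sv_dup$families, function(f) f$n_entries,
                         integer(1)) == 3L))
  expect_true(any(sv_dup$log$reason == "duplicate_temperature"))
})

test_that("written synthetic surveys load back through the entry reader", {
  syn <- generate_survey(generator_config(n_families = 8), seed = 17)
  dir <- withr::local_tempdir()
  write_synthetic_survey(syn, dir)
  back <- read_entries_csv(file.path(dir, "entries.csv"))
  expect_equal(nrow(back), nrow(syn$entries))
  expect_equal(back$refcode, syn$entries$refcode)
  expect_equal(back$temperature_K, syn$entries$temperature_K)
})
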