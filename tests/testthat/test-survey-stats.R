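test_that("histogram bins are half-open, anchored at zero, and conserve counts", {
  h <- build_histogram(c(10, 30, 40), bin_width = 25)
  expect_equal(h$bin_edges, c(0, 25, 50))
  expect_equal(h$counts, c(1L, 2L))
  h0 <- build_histogram(numeric(0))
  expect_equal(h0$n, 0L)
  expect_length(h0$counts, 0)
  # boundary value falls in the upper bin
  expect_equal(build_histogram(c(25), 25)$bin_edges[1], 25)
  set.seed(501)
  x <- rnorm(1e4)
  h2 <- build_histogram(x, 0.5)
  expect_equal(sum(h2$counts), length(x))
  # direct tally oracle
  for (k in sample(seq_along(h2$counts), 5)) {
    expect_equal(h2$counts[k],
                 sum(x >= h2$bin_edges[k] & x < h2$bin_edges[k + 1]))
  }
})

test_that("normal histogram fit recovers generator parameters and amplitude", {
  set.seed(502)
  x <- rnorm(50000, 161, 51)
  h <- build_histogram(x, 25)
  fit <- fit_normal_to_histogram(h)
  expect_equal(fit$mean, 161, tolerance = 2 / 161)
  expect_lt(abs(fit$sd - 51), 2)
  # amplitude ~ N * bin_width at a perfect fit
  expect_equal(fit$amplitude, 50000 * 25, tolerance = 0.02)
  expect_error(fit_normal_to_histogram(build_histogram(c(1, 2, 60, 80), 25)),
               "4 non-empty bins")
})

test_that("skew-normal fit reduces to the normal fit at zero shape and recovers skew", {
  set.seed(503)
  x <- rnorm(30000, 100, 30)
  h <- build_histogram(x, 10)
  nf <- fit_normal_to_histogram(h)
  sf <- fit_skew_normal_to_histogram(h)
  # implied mean/sd of the fitted skew normal close to the plain normal fit
  delta <- sf$shape / sqrt(1 + sf$shape^2)
  implied_mean <- sf$location + sf$scale * delta * sqrt(2 / pi)
  implied_sd <- sf$scale * sqrt(1 - 2 * delta^2 / pi)
  expect_equal(implied_mean, nf$mean, tolerance = 0.02)
  expect_equal(implied_sd, nf$sd, tolerance = 0.05)

  # planted positive skew is recovered with the right sign and parameters
  xi <- 20; om <- 60; al <- 4
  u <- abs(rnorm(40000)); v <- rnorm(40000)
  delta0 <- al / sqrt(1 + al^2)
  z <- delta0 * u + sqrt(1 - delta0^2) * v   # skew-normal draws
  y <- xi + om * z
  hs <- build_histogram(y, 10)
  sf2 <- fit_skew_normal_to_histogram(hs)
  expect_gt(sf2$shape, 0)
  expect_equal(sf2$scale, om, tolerance = 0.1)
  expect_equal(sf2$location, xi, tolerance = 5 / om)
})

test_that("two-half-normal approximation is symmetric at zero shape and continuous at the mode", {
  sym <- structure(list(family = "skew_normal", location = 50, scale = 40,
                        shape = 0, amplitude = 1000, rss = 0),
                   class = "distribution_fit")
  hn <- half_normal_approx(sym)
  expect_equal(hn$centre, 50, tolerance = 1e-6)
  expect_equal(hn$sd_lower, 40, tolerance = 1e-4)
  expect_equal(hn$sd_upper, 40, tolerance = 1e-4)

  skew <- structure(list(family = "skew_normal", location = 0, scale = 60,
                         shape = 4, amplitude = 1000, rss = 0),
                    class = "distribution_fit")
  hn2 <- half_normal_approx(skew)
  expect_gt(hn2$sd_upper, hn2$sd_lower)
  # composite density equals the skew-normal density at the centre exactly
  expect_equal(hn2$amplitude,
               1000 * dskewnorm(hn2$centre, 0, 60, 4), tolerance = 1e-9)
})

test_that("sigma thresholds reproduce the printed survey bounds", {
  nf <- structure(list(family = "normal", mean = 161, sd = 51,
                       amplitude = 1, rss = 0), class = "distribution_fit")
  expect_equal(sigma_thresholds(nf, 3), c(lower = 8, upper = 314))
  thn <- structure(list(family = "two_half_normal", centre = 33,
                        sd_lower = 40, sd_upper = 56, amplitude = 1, rss = 0),
                   class = "distribution_fit")
  expect_equal(sigma_thresholds(thn, 3), c(lower = -87, upper = 201))
  expect_equal(sigma_thresholds(nf, 0), c(lower = 161, upper = 161))
  # monotone in k
  ks <- 0:4
  th <- vapply(ks, function(k) sigma_thresholds(nf, k), numeric(2))
  expect_true(all(diff(th["upper", ]) > 0))
  expect_true(all(diff(th["lower", ]) < 0))
})

test_that("linearity screen flags planted errors and supports outlier diagnosis", {
  cfg <- survey_config()
  entries <- validate_entries(isotropic_family_entries(
    temps = c(100, 150, 200, 250, 293)))
  fam <- partition_refcode_family(entries)$families[[1]]
  scr <- linearity_screen(list(fam), 0.96, cfg)
  expect_length(scr$passed, 1)

  # one temperature mislabelled by +100 K ruins the fit; dropping the
  # worst-residual point restores it
  bad <- entries
  bad$temperature_K[2] <- bad$temperature_K[2] + 100
  fam_bad <- partition_refcode_family(bad)$families[[1]]
  scr2 <- linearity_screen(list(fam_bad), 0.96, cfg)
  expect_length(scr2$failed, 1)
  worst <- scr2$failed[[1]]$diagnostics$refcode[1]
  expect_equal(worst, bad$refcode[2])
  fixed <- bad[bad$refcode != worst, ]
  fam_fixed <- partition_refcode_family(fixed)$families[[1]]
  expect_length(linearity_screen(list(fam_fixed), 0.96, cfg)$passed, 1)

  # a volume jump mid-range (phase transition) also fails the screen
  jump <- isotropic_family_entries(temps = c(100, 150, 200, 250, 293))
  for (i in 4:5) {
    jump[i, c("a", "b", "c")] <- jump[i, c("a", "b", "c")] * 1.01
  }
  fam_jump <- partition_refcode_family(validate_entries(jump))$families[[1]]
  expect_length(linearity_screen(list(fam_jump), 0.96, cfg)$failed, 1)
})

test_that("outlier tables isolate planted extremes and suspect negatives", {
  mk_row <- function(id, alpha_v, n, r2, aniso = 0.4, two = n == 2) {
    data.frame(family_id = id, n_points = n, t_min = 100, t_max = 293,
               alpha_v = alpha_v, su_alpha_v = NA, r2_v = r2,
               alpha_l1 = alpha_v / 3, alpha_l2 = alpha_v / 3,
               alpha_l3 = alpha_v / 3, su_l1 = NA, su_l2 = NA, su_l3 = NA,
               axis1_x = 1, axis1_y = 0, axis1_z = 0, axis2_x = 0,
               axis2_y = 1, axis2_z = 0, axis3_x = 0, axis3_y = 0,
               axis3_z = 1, anisotropy = aniso, nte_class = "none",
               two_point = two, stringsAsFactors = FALSE)
  }
  rt <- rbind(mk_row("extreme", 400, 5, 0.99),
              mk_row("typical", 160, 3, 0.99),
              mk_row("pressure2pt", -150, 2, NA),
              mk_row("aniso", 180, 4, 0.99, aniso = 4.2))
  out <- tabulate_outliers(rt, c(lower = 8, upper = 314), min_points = 4,
                           anisotropy_ref = 3.2, r2_min = 0.96)
  expect_equal(out$high_alpha_v$family_id, "extreme")
  expect_equal(out$low_alpha_v$family_id, "pressure2pt")
  expect_true(out$low_alpha_v$suspect)
  expect_equal(out$extreme_anisotropy$family_id, "aniso")
  # no extremes -> empty tables
  out2 <- tabulate_outliers(rt[2, , drop = FALSE], c(lower = 8, upper = 314))
  expect_equal(nrow(out2$high_alpha_v), 0)
  expect_equal(nrow(out2$low_alpha_v), 0)
  expect_equal(nrow(out2$extreme_anisotropy), 0)
})
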