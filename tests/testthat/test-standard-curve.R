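test_that("noiseless dilution series is recovered exactly", {
  std <- noiseless_standards(-3.321928, 38, copies = 10^(1:7), reps = 1L)
  sc <- suppressWarnings(fit_standard_curve(std))
  expect_equal(sc$slope, -3.321928, tolerance = 1e-8)
  expect_equal(sc$intercept, 38, tolerance = 1e-8)
  expect_equal(sc$efficiency_pct, 100, tolerance = 1e-4)
  expect_equal(sc$r_squared, 1, tolerance = 1e-10)
  expect_length(sc$warnings, 0)

  sc2 <- suppressWarnings(
    fit_standard_curve(noiseless_standards(-3.4149, 37.5)))
  expect_equal(sc2$efficiency_pct, 96.26, tolerance = 1e-4)
})

test_that("efficiency formula matches its closed form", {
  expect_equal(efficiency_from_slope(-1 / log10(2)), 100)
  expect_equal(efficiency_from_slope(-3.4149), 96.26, tolerance = 1e-4)
  expect_equal(efficiency_from_slope(-3.1), 110.17, tolerance = 1e-4)
  expect_error(efficiency_from_slope(3.3), "negative")
  expect_error(efficiency_from_slope(0), "negative")
})

test_that("out-of-window efficiency is flagged, not fatal", {
  sc <- suppressWarnings(
    fit_standard_curve(noiseless_standards(-3.1, 37, reps = 1L)))
  expect_match(sc$warnings, "outside accepted range")
  expect_equal(sc$efficiency_pct, 110.17, tolerance = 1e-4)
})

test_that("degenerate calibration designs are rejected", {
  one_conc <- data.frame(known_copies = rep(100, 5), cq = rnorm(5, 30, 0.1))
  expect_error(fit_standard_curve(one_conc), "3 distinct")
  two_conc <- data.frame(known_copies = rep(c(10, 100), each = 3),
                         cq = rep(c(34, 31), each = 3))
  expect_error(fit_standard_curve(two_conc), "3 distinct")
  all_nd <- data.frame(known_copies = 10^(1:5), cq = NA_real_)
  expect_error(fit_standard_curve(all_nd), "non-detect")
})

test_that("non-detect standards are excluded from the fit", {
  std <- noiseless_standards(-3.4149, 37.5, copies = 10^(1:5), reps = 2L)
  std$cq[std$known_copies == 10][1] <- NA  # one dropped well
  sc <- suppressWarnings(fit_standard_curve(std))
  expect_equal(sc$n_points, 9L)
  expect_equal(sc$slope, -3.4149, tolerance = 1e-8)
})

test_that("cq_to_copies inverts the calibration line", {
  sc <- fixture_curve()
  expect_equal(cq_to_copies(sc$intercept, sc), 1.0, tolerance = 1e-10)
  sc38 <- suppressWarnings(fit_standard_curve(
    noiseless_standards(-3.321928, 38, reps = 1L)))
  expect_equal(cq_to_copies(28.0342, sc38), 1000, tolerance = 1e-4)
  q <- 10^seq(0, 8, by = 0.5)
  round_trip <- cq_to_copies(copies_to_cq(q, sc), sc)
  expect_lt(max(abs(round_trip - q) / q), 1e-10)
  # strictly decreasing in cq
  cqs <- seq(20, 40, by = 0.5)
  expect_true(all(diff(cq_to_copies(cqs, sc)) < 0))
  expect_warning(cq_to_copies(50, sc, warn_extrapolation = TRUE),
                 "extrapolation")
})

test_that("slope is recovered under Cq measurement noise", {
  set.seed(101)
  cfg <- simulation_config(
    standards = data.frame(copies = 10^(2:8), n_replicates = 10L),
    cq_noise_sd = 0.2)
  sc <- fit_standard_curve(simulate_dilution_series(cfg))
  expect_lt(abs(sc$slope - cfg$curve_slope), 0.05)
  expect_gt(sc$r_squared, 0.99)
})

test_that("mass-to-copies conversion follows the Avogadro formula", {
  expect_equal(ng_to_copies(0, 3000), 0)
  expect_equal(ng_to_copies(1, 3000), 3.041e8, tolerance = 1e-3)
  expect_equal(ng_to_copies(1, 6000) * 2, ng_to_copies(1, 3000))
  expect_error(ng_to_copies(1, 0), "positive")
  expect_error(ng_to_copies(-1, 100), "non-negative")
})

test_that("volume configuration is validated", {
  expect_error(volume_config(template_volume = 0), "positive")
  expect_error(volume_config(template_volume = 60), "exceed")
  v <- volume_config()
  expect_s3_class(v, "volume_config")
  expect_equal(v$elution_volume / v$template_volume / v$filtration_volume, 50)
})
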