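test_that("detection summaries count detects and replicates", {
  std <- data.frame(known_copies = rep(c(1, 100), each = 10),
                    cq = c(ifelse(1:10 <= 6, 30, NA), rnorm(10, 25, 0.1)))
  det <- summarize_detections(std)
  expect_equal(det$copies, c(1, 100))
  expect_equal(det$n_replicates, c(10L, 10L))
  expect_equal(det$n_detected, c(6L, 10L))
  expect_error(summarize_detections(std[0, ]), "no standard")
})

test_that("LOD solves the single-hit Poisson model in closed form", {
  # deterministic counts lying exactly on p = 1 - exp(-Q): LOD -> -ln(0.05)
  q <- c(0.5, 1, 2, 3, 4, 6, 8)
  det <- data.frame(copies = q, n_replicates = 1e6,
                    n_detected = round(1e6 * (1 - exp(-q))),
                    p_detected = NA_real_)
  lod <- estimate_lod(det)
  expect_equal(lod$model, "poisson_cloglog")
  expect_false(lod$censored)
  expect_equal(unname(lod$lod_copies), -log(0.05), tolerance = 1e-3)
  expect_equal(round(unname(lod$lod_copies)), 3)

  # halved per-molecule efficiency doubles the LOD: -ln(0.05)/0.5
  det2 <- data.frame(copies = 2 * q, n_replicates = 1e6,
                     n_detected = round(1e6 * (1 - exp(-0.5 * 2 * q))),
                     p_detected = NA_real_)
  lod2 <- estimate_lod(det2)
  expect_equal(unname(lod2$lod_copies), -log(0.05) / 0.5, tolerance = 1e-2)
})

test_that("saturated detection censors the LOD at the lowest standard", {
  det <- data.frame(copies = 10^(1:5), n_replicates = 10,
                    n_detected = 10, p_detected = 1)
  lod <- estimate_lod(det)
  expect_true(lod$censored)
  expect_equal(lod$lod_copies, 10)
})

test_that("LOD errors and the discrete criterion behave", {
  none <- data.frame(copies = c(1, 10), n_replicates = 10,
                     n_detected = 0L, p_detected = 0)
  expect_error(estimate_lod(none), "undefined")

  det <- data.frame(copies = c(1, 3, 10, 100), n_replicates = 20,
                    n_detected = c(10, 17, 19, 20), p_detected = NA)
  disc <- estimate_lod(det, method = "discrete")
  expect_equal(disc$lod_copies, 10)  # first level with >= 95% observed
  expect_equal(disc$model, "discrete")
})

test_that("LOD is non-increasing in per-molecule efficiency", {
  set.seed(202)
  q <- c(1, 2, 4, 8, 16, 32, 64)
  lods <- vapply(c(0.3, 0.6, 1.0), function(eff) {
    unname(estimate_lod(poisson_detections(q, 2000L, eff))$lod_copies)
  }, numeric(1))
  expect_true(all(diff(lods) < 0))
})

test_that("LOQ crossing matches each generating model in closed form", {
  curve <- fixture_curve()

  # exponential decay: a e^{-bQ} = t at Q = ln(a/t)/b
  std_exp <- cv_standards(curve, c(1, 5, 10, 20, 50, 100),
                          function(q) 0.9 * exp(-0.03 * q))
  loq <- estimate_loq(std_exp, curve)
  expect_equal(loq$model, "exponential_decay")
  expect_false(loq$censored)
  expect_equal(loq$loq_copies, log(0.9 / 0.35) / 0.03, tolerance = 1e-3)

  # linear in log10 Q: crossing at 10^{(a - t)/b}
  std_lin <- cv_standards(curve, 10^seq(0, 2, by = 0.5),
                          function(q) 0.95 - 0.4 * log10(q))
  loq_lin <- estimate_loq(std_lin, curve)
  expect_equal(loq_lin$model, "linear")
  expect_equal(loq_lin$loq_copies, 10^1.5, tolerance = 1e-3)

  # quadratic in log10 Q: first root of the threshold equation
  cvq <- function(q) 0.9 - 0.5 * log10(q) + 0.08 * log10(q)^2
  std_poly <- cv_standards(curve, 10^(0:4), cvq)
  loq_poly <- estimate_loq(std_poly, curve)
  expect_equal(loq_poly$model, "polynomial2")
  root <- (0.5 - sqrt(0.5^2 - 4 * 0.08 * 0.55)) / (2 * 0.08)
  expect_equal(loq_poly$loq_copies, 10^root, tolerance = 1e-3)
})

test_that("LOQ is censored when the CV threshold is met at the extremes", {
  curve <- fixture_curve()
  low_cv <- cv_standards(curve, 10^(1:4), function(q) 0.10)
  loq <- estimate_loq(low_cv, curve)
  expect_true(loq$censored)
  expect_equal(loq$loq_copies, 10)

  high_cv <- cv_standards(curve, 10^(1:4), function(q) 0.6 - 0.05 * log10(q))
  expect_warning(loq_hi <- estimate_loq(high_cv, curve), "censored")
  expect_true(loq_hi$censored)
  expect_equal(loq_hi$loq_copies, 1e4)
})

test_that("CV requires replication", {
  curve <- fixture_curve()
  singletons <- data.frame(known_copies = 10^(1:4),
                           cq = copies_to_cq(10^(1:4), curve))
  expect_error(summarize_cv(singletons, curve), "singleton")
})

test_that("joint sensitivity enforces LOD <= LOQ with a note", {
  curve <- fixture_curve()
  set.seed(303)
  cfg <- simulation_config(seed = 303)
  std <- simulate_dilution_series(cfg)
  sens <- estimate_sensitivity(std)
  expect_s3_class(sens, "sensitivity_result")
  expect_lte(sens$lod_copies, sens$loq_copies)

  # engineered disagreement: tight CVs everywhere but sparse detection
  std_cv <- cv_standards(curve, c(4, 16, 64, 256), function(q) 0.05)
  det_sparse <- rbind(std_cv,
                      data.frame(known_copies = rep(4, 20),
                                 cq = c(rep(NA, 8), copies_to_cq(rep(4, 12), curve))))
  sens2 <- estimate_sensitivity(det_sparse, curve)
  expect_lte(sens2$lod_copies, sens2$loq_copies)
})
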