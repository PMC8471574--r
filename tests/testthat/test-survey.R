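test_that("gating partitions reactions into exactly one status", {
  expect_equal(as.character(classify_detection(0, 4.11, 30)), "negative")
  expect_equal(as.character(classify_detection(15, 4.11, 30)),
               "detected_below_loq")
  expect_equal(as.character(classify_detection(45, 4.11, 30)), "quantifiable")
  # boundaries: at LOD -> negative ("greater than the LOD" is positive),
  # at LOQ -> quantifiable
  expect_equal(as.character(classify_detection(4.11, 4.11, 30)), "negative")
  expect_equal(as.character(classify_detection(30, 4.11, 30)), "quantifiable")
  copies <- c(0, 2, 4.11, 10, 29.9, 30, 1000)
  st <- classify_detection(copies, 4.11, 30)
  expect_false(any(is.na(st)))  # a partition: every reaction gets a status
  expect_error(classify_detection(1, 30, 4.11), "lod > loq")
})

test_that("a site is positive when any replicate exceeds the LOD", {
  expect_true(site_detection(c("negative", "negative", "quantifiable")))
  expect_true(site_detection(c("detected_below_loq", "negative", "negative")))
  expect_false(site_detection(rep("negative", 3)))
  expect_error(site_detection(character(0)), "no replicate")
})

test_that("copies per liter conversion is the volume ratio, and linear", {
  v <- volume_config()
  expect_equal(copies_per_liter(0, v), 0)
  expect_equal(copies_per_liter(100, v), 5000)
  v2 <- volume_config(filtration_volume = 1)
  expect_equal(copies_per_liter(100, v2), 2500)
  expect_equal(copies_per_liter(3 + 7, v),
               copies_per_liter(3, v) + copies_per_liter(7, v))
})

test_that("log10(x+1) transform anchors zero and known points", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(99), 2)
  expect_equal(log_transform(1.09e6), 6.0374, tolerance = 1e-4)
  expect_error(log_transform(-1), "non-negative")
})

test_that("fold changes reproduce the published seasonal ratios", {
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(1.09e6, 1.71e4), 63.60, tolerance = 0.003)
  expect_equal(fold_change(1.71e4, 1.96e3), 8.70, tolerance = 0.003)
  expect_warning(fc <- fold_change(1, 0), "censored")
  expect_true(is.infinite(fc))
})

test_that("group summaries follow the negative-fill rule", {
  q <- data.frame(assay = "sp", site = "site1", season = "s", replicate = 1:3,
                  status = c("negative", "quantifiable", "quantifiable"),
                  copies_per_liter = c(10, 6000, 8000),
                  log_copies = log10(c(10, 6000, 8000) + 1))
  q$status <- factor(q$status,
                     levels = c("negative", "detected_below_loq", "quantifiable"))
  s <- summarize_survey(q, group_keys = c("assay", "site", "season"))
  expect_true(s$detected)
  expect_equal(s$mean_copies_per_liter, (0 + 6000 + 8000) / 3, tolerance = 1e-10)
  expect_equal(s$n_quantifiable, 2L)

  s_omit <- summarize_survey(q, group_keys = c("assay", "site", "season"),
                             negative_fill = "omit")
  expect_equal(s_omit$mean_copies_per_liter, 7000)

  q$status[] <- "negative"
  s_neg <- summarize_survey(q, group_keys = c("assay", "site", "season"))
  expect_false(s_neg$detected)
  expect_equal(s_neg$mean_copies_per_liter, 0)

  # below-LOQ detections count as detections but not toward means
  q$status[] <- c("detected_below_loq", "negative", "quantifiable")
  s_mix <- summarize_survey(q, group_keys = c("assay", "site", "season"))
  expect_true(s_mix$detected)
  expect_equal(s_mix$n_detected, 2L)
  expect_equal(s_mix$mean_copies_per_liter, (0 + 8000) / 2)

  expect_error(summarize_survey(q, group_keys = "nope"), "unknown group key")
})

test_that("quantification is monotone in raw copies end to end", {
  curve <- fixture_curve()
  sens <- structure(list(lod_copies = 4, loq_copies = 30,
                         lod_model = "poisson_cloglog",
                         loq_model = "exponential_decay",
                         lod_censored = FALSE, loq_censored = FALSE,
                         probability = 0.95, cv_threshold = 0.35,
                         fit_diagnostics = NULL, cv_table = NULL,
                         notes = character(0)),
                    class = "sensitivity_result")
  copies <- c(1, 5, 50, 500)
  plate <- data.frame(sample_id = paste0("s", 1:4), replicate = 1L,
                      assay = "sp", reaction_type = "unknown",
                      cq = copies_to_cq(copies, curve))
  out <- quantify_survey(plate, curve, sens)
  expect_equal(out$raw_copies, copies, tolerance = 1e-8)
  expect_true(all(diff(out$copies_per_liter) > 0))
  expect_equal(as.character(out$status),
               c("negative", "detected_below_loq", "quantifiable",
                 "quantifiable"))
  # status rank never decreases with raw copies
  expect_true(all(diff(as.integer(out$status)) >= 0))
})

test_that("reactions without a finite IPC correction are excluded", {
  curve <- fixture_curve()
  sens <- structure(list(lod_copies = 4, loq_copies = 30,
                         lod_model = "poisson_cloglog",
                         loq_model = "exponential_decay",
                         lod_censored = FALSE, loq_censored = FALSE,
                         probability = 0.95, cv_threshold = 0.35,
                         fit_diagnostics = NULL, cv_table = NULL,
                         notes = character(0)),
                    class = "sensitivity_result")
  plate <- data.frame(sample_id = c("a", "b"), site = c("s1", "s2"),
                      season = "x", replicate = 1L, assay = "sp",
                      reaction_type = "unknown",
                      cq = copies_to_cq(c(100, 100), curve))
  ih <- data.frame(site = c("s1", "s2"), season = "x",
                   delta_cq = c(1, Inf))
  expect_warning(out <- quantify_survey(plate, curve, sens, ih),
                 "non-amplified sample IPC")
  expect_equal(out$normalized_copies[1], 200, tolerance = 1e-6)
  expect_true(is.na(out$status[2]))
})
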