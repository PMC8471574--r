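test_that("generation is bitwise-reproducible under a fixed seed", {
  cfg <- simulation_config(seed = 42)
  expect_identical(simulate_dilution_series(cfg), simulate_dilution_series(cfg))
  s1 <- simulate_scenario("yangyang-default", seed = 9)
  s2 <- simulate_scenario("yangyang-default", seed = 9)
  expect_identical(s1$plate, s2$plate)
  s3 <- simulate_scenario("yangyang-default", seed = 10)
  expect_false(identical(s1$plate, s3$plate))
})

test_that("detection and CV follow Poisson single-molecule statistics", {
  set.seed(606)
  cfg3 <- simulation_config(standards = data.frame(copies = 3,
                                                   n_replicates = 4000L))
  plate <- simulate_dilution_series(cfg3)
  det <- summarize_detections(plate)
  expect_equal(det$p_detected, 1 - exp(-3), tolerance = 0.02)

  # noiseless Cq: replicate CV of back-calculated copies is the Poisson CV
  cfg1000 <- simulation_config(cq_noise_sd = 0,
                               standards = data.frame(copies = 1000,
                                                      n_replicates = 3000L))
  plate2 <- simulate_dilution_series(cfg1000)
  curve <- fixture_curve()
  cv <- summarize_cv(plate2, curve)
  expect_equal(cv$cv, 1 / sqrt(1000), tolerance = 0.1)
})

test_that("an absent species yields only non-detects", {
  design <- yangyang_design()
  design$species_means$mean_copies_per_liter[
    design$species_means$assay == "O_kisutch"] <- 0
  set.seed(607)
  plate <- simulate_field_survey(design, simulation_config())
  kis <- plate[plate$assay == "O_kisutch" & plate$reaction_type == "unknown", ]
  expect_gt(nrow(kis), 0)
  expect_true(all(is.na(kis$cq)))
})

test_that("salinity-driven inhibition induces a positive correlation", {
  sites <- data.frame(site = paste0("s", 1:8),
                      stream_class = "mainstem",
                      salinity = seq(0, 7, by = 1))
  means <- data.frame(assay = "sp", season = "one",
                      mean_copies_per_liter = 1e5)
  design <- survey_design(sites, means, salinity_inhibition_slope = 0.25)
  set.seed(608)
  plate <- simulate_field_survey(design, simulation_config())
  ih <- inhibition_table(plate, by = c("site", "season"))
  sal <- sites$salinity[match(ih$site, sites$site)]
  res <- spearman_correlation(ih$delta_cq, sal)
  expect_gt(res$statistic, 0.5)
})

test_that("the default survey design encodes the study structure", {
  design <- yangyang_design()
  expect_equal(nrow(design$sites), 6)
  expect_equal(design$sites$stream_class,
               c(rep("mainstem", 3), rep("tributary", 3)))
  expect_equal(design$replicate_count, 3L)
  expect_setequal(design$seasons, c("spawning", "non_spawning"))
  keta <- design$species_means[design$species_means$assay == "O_keta", ]
  ratio <- keta$mean_copies_per_liter[keta$season == "spawning"] /
    keta$mean_copies_per_liter[keta$season == "non_spawning"]
  expect_equal(ratio, 63.74, tolerance = 1e-3)
  expect_equal(range(design$inhibition_delta$delta_cq), c(-0.33, 1.33))
})

test_that("scenario plates carry every layer the pipeline needs", {
  scen <- simulate_scenario("yangyang-default", seed = 3)
  plate <- scen$plate
  expect_setequal(unique(plate$reaction_type),
                  c("standard", "unknown", "ipc_sample", "ipc_control", "ntc"))
  expect_equal(length(setdiff(unique(plate$assay), "IPC")), 4)
  # 4 assays x 6 sites x 2 seasons x 3 replicates unknown wells
  expect_equal(sum(plate$reaction_type == "unknown"), 4 * 6 * 2 * 3)
  expect_true(all(is.na(plate$cq[plate$reaction_type == "ntc"])))
})
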