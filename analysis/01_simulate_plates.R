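#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study plates.
#
# Produces the combined plate table the rest of the workflow consumes:
# a ten-replicate, seven-decade dilution series per assay plus a
# six-site x two-season x four-assay field survey with IPC wells and
# no-template controls. Ground truth (the injected design) is saved for
# the recovery checks in later stages.

suppressPackageStartupMessages(library(ednaqpcr))

seed <- 1L
dir.create("results", showWarnings = FALSE)

scen <- simulate_scenario("yangyang-default", seed = seed)
write_plate_table(scen$plate, "results/plate.tsv")

truth <- scen$truth
jsonlite::write_json(
  list(seed = truth$seed,
       sites = truth$design$sites,
       species_means = truth$design$species_means,
       inhibition_delta = truth$design$inhibition_delta,
       curve = list(slope = truth$config$curve_slope,
                    intercept = truth$config$curve_intercept),
       cq_noise_sd = truth$config$cq_noise_sd),
  "results/ground_truth.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

n_std <- sum(scen$plate$reaction_type == "standard")
n_unk <- sum(scen$plate$reaction_type == "unknown")
cat(sprintf("Simulated plate written: %d reactions (%d standards, %d field, %d IPC/NTC)\n",
            nrow(scen$plate), n_std, n_unk, nrow(scen$plate) - n_std - n_unk))
cat("Outputs: results/plate.tsv, results/ground_truth.json\n")
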