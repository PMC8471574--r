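#!/usr/bin/env Rscript
# Stage 2: standard curves and assay sensitivity.
#
# Fits each assay's Cq ~ log10(copies) calibration from its dilution
# series, then models the limit of detection (95% detection probability)
# and the limit of quantification (35% CV threshold). Also prints the
# single-hit Poisson theoretical LOD these estimates are benchmarked
# against, and the reference panel summary.

suppressPackageStartupMessages(library(ednaqpcr))

plate <- read_plate_table("results/plate.tsv")
assays <- setdiff(unique(plate$assay[plate$reaction_type == "standard"]), "IPC")

sens_report <- list()
for (a in assays) {
  std <- plate[plate$assay == a & plate$reaction_type == "standard", ]
  curve <- fit_standard_curve(std)
  sens <- estimate_sensitivity(std, curve)
  cat(sprintf("%-10s slope %.3f  eff %.2f%%  r2 %.4f  LOD %5.2f (%s)  LOQ %6.2f (%s)\n",
              a, curve$slope, curve$efficiency_pct, curve$r_squared,
              sens$lod_copies, sens$lod_model,
              sens$loq_copies, sens$loq_model))
  sens_report[[a]] <- list(
    slope = curve$slope, intercept = curve$intercept,
    efficiency_pct = curve$efficiency_pct, r_squared = curve$r_squared,
    lod_copies = sens$lod_copies, loq_copies = sens$loq_copies,
    lod_model = sens$lod_model, loq_model = sens$loq_model,
    lod_censored = sens$lod_censored, loq_censored = sens$loq_censored)
}
jsonlite::write_json(sens_report, "results/sensitivity_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("\nTheoretical single-hit Poisson LOD at 95%%: %.3f copies (~3)\n",
            -log(0.05)))
panel <- assay_panel_summary()
cat(sprintf("Reference panel: mean LOD %.3f copies over %d assays\n",
            panel$mean_lod, panel$n_assays))
cat("Output: results/sensitivity_report.json\n")
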