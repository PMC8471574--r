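#!/usr/bin/env Rscript
# Stage 5: rank-based group comparisons.
#
# Pairwise Wilcoxon rank-sum tests on log10(x+1) copies/L across the three
# comparison families -- species within season, season within species,
# mainstem vs tributary -- with Holm adjustment per family.

suppressPackageStartupMessages(library(ednaqpcr))

quantified <- read.table("results/quantified.tsv", header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
quantified$status <- factor(quantified$status,
                            levels = c("negative", "detected_below_loq",
                                       "quantifiable"))
cmp <- compare_groups(quantified, adjust = "holm")
write.table(cmp, "results/comparisons.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat("Significant comparisons (Holm-adjusted):\n")
sig <- cmp[cmp$stars != "ns", ]
print(sig[c("family", "group_a", "group_b", "p_adjusted", "stars")],
      row.names = FALSE, digits = 3)

seas <- cmp[grepl("^season_within_O_keta", cmp$family), ]
cat(sprintf("\nO_keta season contrast: p_adj = %.3g (%s)\n",
            seas$p_adjusted, seas$stars))
cat("Output: results/comparisons.tsv\n")
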