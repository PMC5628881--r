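#!/usr/bin/env Rscript

# Step 2: discovery — filter the genotype matrix, detect and mask reference
# introgressions, and select the diagnostic-polymorphism (DP) panel.
#
# Reads results/genotypes.tsv + results/sample_panel.tsv (from step 1) and
# writes the mask set, per-locus statistics and the DP panel.

suppressPackageStartupMessages(library(phylokaryo))

out <- "results"
gm <- read_genotype_table(file.path(out, "genotypes.tsv"))
panel <- read_sample_panel(file.path(out, "sample_panel.tsv"))

disc <- run_discovery(gm, panel)

write_mask_set(disc$masks, file.path(out, "reference_masks.tsv"))
write_locus_stats(disc$stats, file.path(out, "locus_stats.tsv"))
write_diagnostic_panel(disc$dp_panel, file.path(out, "dp_panel.tsv"))
write_genotype_table(disc$gm_filtered, file.path(out, "genotypes_filtered.tsv"))

# before/after view of the masking effect on the DP count
unmasked <- run_discovery(gm, panel, mask = FALSE)
cat(sprintf("loci after filters: %d\n", nrow(disc$gm_filtered$loci)))
cat(sprintf("reference introgression intervals masked: %d\n",
            nrow(disc$masks)))
cat(sprintf("DPs selected: %d (masked) vs %d (unmasked)\n",
            nrow(disc$dp_panel), nrow(unmasked$dp_panel)))
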