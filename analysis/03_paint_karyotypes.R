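#!/usr/bin/env Rscript

# Step 3: painting — classify every sample's genotype calls against the DP
# panel, call 20-DP ancestry windows, merge them into phylogenomic-karyotype
# segments and estimate genome-wide admixture proportions.

suppressPackageStartupMessages(library(phylokaryo))

out <- "results"
gm <- read_genotype_table(file.path(out, "genotypes_filtered.tsv"))
dps <- read_diagnostic_panel(file.path(out, "dp_panel.tsv"))

paint <- run_painting(gm, dps)

write_karyotype_segments(paint$segments, file.path(out, "karyotype_segments.tsv"))
write_admixture(paint$admixture, file.path(out, "admixture.tsv"))
utils::write.table(paint$windows, file.path(out, "karyotype_windows.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

queries <- read_sample_panel(file.path(out, "sample_panel.tsv"))
queries <- queries$sample[queries$role == "QUERY"]
p <- plot_karyotype(paint$segments[paint$segments$sample %in% queries, ])
ggplot2::ggsave(file.path(out, "karyotypes.pdf"), p,
                width = 10, height = 1.2 * length(queries), limitsize = FALSE)

adm <- paint$admixture[paint$admixture$sample %in% queries, ]
cat("admixture proportions (queries):\n")
print(adm, row.names = FALSE)
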