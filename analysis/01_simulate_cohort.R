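#!/usr/bin/env Rscript

# Step 1: simulate the study cohort.
#
# Generates the two-taxon ancestral model, a reference panel (with two
# introgressed reference accessions, as real germplasm panels carry), and a
# set of admixed query varieties with known ancestry, then writes the
# genotype matrix, sample panel and ground truth under results/.

suppressPackageStartupMessages(library(phylokaryo))

out <- "results"
dir.create(out, showWarnings = FALSE)

model <- simulate_ancestral_model(seed = 101)

intro_block <- function(own, chrom, from, to) {
  other <- if (own == "RET") "MAX" else "RET"
  b <- NULL
  for (ch in names(model$chrom_lengths)) {
    len <- model$chrom_lengths[[ch]]
    if (ch == chrom) {
      mid <- data.frame(start = c(1, from, to + 1),
                        end = c(from - 1, to, len),
                        taxon = c(own, other, own))
      mid <- mid[mid$start <= mid$end, ]
      b <- rbind(b, cbind(chrom = ch, homolog = 1L, mid),
                 data.frame(chrom = ch, homolog = 2L, start = 1, end = len,
                            taxon = own))
    } else {
      b <- rbind(b, data.frame(chrom = ch, homolog = 1:2, start = 1,
                               end = len, taxon = own))
    }
  }
  spec_blocks(model, b)
}

refs <- simulate_reference_panel(
  model,
  introgressions = list(RET_04 = intro_block("RET", "2", 6e6, 1.8e7),
                        MAX_02 = intro_block("MAX", "5", 1.2e7, 2.5e7)),
  seed = 102)

specs <- list(
  TANGOR_F1 = spec_f1(model),
  MANDARIN = spec_pure(model, "RET"),
  PUMMELO = spec_pure(model, "MAX"),
  BC1_RET = spec_bc(model, 1, "RET", seed = 103),
  BC3_RET = spec_bc(model, 3, "RET", seed = 104),
  BC6_RET = spec_bc(model, 6, "RET", seed = 105))
queries <- simulate_queries(model, specs, seed = 106)

gm <- bind_samples(refs$genotypes, queries$genotypes)
gm <- inject_missingness(gm, rate = 0.126, seed = 107)
panel <- rbind(refs$panel,
               data.frame(sample = names(specs), role = "QUERY"))

write_genotype_table(gm, file.path(out, "genotypes.tsv"))
write_sample_panel(panel, file.path(out, "sample_panel.tsv"))
saveRDS(list(model = model, specs = specs,
             reference_truth = refs$truth,
             query_prop_max = queries$prop_max),
        file.path(out, "truth.rds"))

cat(sprintf("cohort: %d samples x %d loci -> %s\n",
            length(gm$samples), nrow(gm$loci), out))
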