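# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# tiny genotype matrix from a bare dosage matrix (rows = samples)
toy_gm <- function(dosage, chrom = NULL, pos = NULL,
                   class = NULL, anchor = NULL) {
  n <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%02d", seq_len(nrow(dosage)))
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(class)) class <- rep("SNP", n)
  if (is.null(anchor)) anchor <- class == "INDEL"
  genotype_matrix(dosage, data.frame(
    chrom = chrom, pos = pos,
    ref = rep("A", n), alt = ifelse(class == "SNP", "G", "AG"),
    class = class, indel_anchor = anchor, stringsAsFactors = FALSE))
}

# a small two-taxon cohort: references (optionally introgressed), queries
# with known ancestry, optional missingness
toy_cohort <- function(seed, n_chrom = 3L, loci_per_chrom = 600L,
                       n_ret = 11L, n_max = 6L, introgressions = NULL,
                       query_specs = NULL, miss_rate = 0) {
  model <- simulate_ancestral_model(n_chrom = n_chrom,
                                    loci_per_chrom = loci_per_chrom,
                                    seed = seed)
  refs <- simulate_reference_panel(model, n_ret, n_max,
                                   introgressions = introgressions,
                                   seed = seed + 1L)
  gm <- refs$genotypes
  panel <- refs$panel
  truth <- refs$truth
  prop_max <- NULL
  if (!is.null(query_specs)) {
    q <- simulate_queries(model, query_specs, seed = seed + 2L)
    gm <- bind_samples(gm, q$genotypes)
    panel <- rbind(panel, data.frame(sample = names(query_specs),
                                     role = "QUERY",
                                     stringsAsFactors = FALSE))
    truth <- c(truth, q$truth)
    prop_max <- q$prop_max
  }
  if (miss_rate > 0) gm <- inject_missingness(gm, miss_rate, seed = seed + 3L)
  list(model = model, gm = gm, panel = panel, truth = truth,
       prop_max = prop_max)
}

# explicit heterozygous (or homozygous) other-taxon block in one reference
introgression_spec <- function(model, own, chrom, from, to,
                               homozygous = FALSE) {
  other <- if (own == "RET") "MAX" else "RET"
  len <- model$chrom_lengths[[chrom]]
  blk <- function(taxon_mid, homolog) {
    pieces <- data.frame(
      start = c(1, from, min(to + 1, len + 1)),
      end = c(from - 1, to, len),
      taxon = c(own, taxon_mid, own), stringsAsFactors = FALSE)
    pieces <- pieces[pieces$start <= pieces$end, , drop = FALSE]
    cbind(chrom = chrom, homolog = homolog, pieces, stringsAsFactors = FALSE)
  }
  b <- rbind(blk(other, 1L),
             if (homozygous) blk(other, 2L) else blk(own, 2L))
  whole <- NULL
  for (ch in setdiff(names(model$chrom_lengths), chrom)) {
    l <- model$chrom_lengths[[ch]]
    whole <- rbind(whole, data.frame(chrom = ch, homolog = 1:2, start = 1,
                                     end = l, taxon = own,
                                     stringsAsFactors = FALSE))
  }
  spec_blocks(model, rbind(b, whole))
}
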