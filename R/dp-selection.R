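# Re-estimation of taxon allele frequencies on masked references and
# selection of the diagnostic-polymorphism (DP) panel.

#' Inter-taxon G_ST per locus from (masked) reference data
#'
#' Allele frequencies of each reference taxon are estimated treating calls
#' inside the introgression mask as missing, then Nei's equal-weight G_ST is
#' computed per locus. Passing an empty/`NULL` mask gives the first-pass
#' (unmasked) values for before/after comparison.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param panel Sample panel data frame.
#' @param mask Optional mask set from [scan_reference_introgressions()].
#' @return Data frame `chrom pos p_ret p_max n_ret n_max gst` (frequencies
#'   are alt-allele frequencies; `gst` is `NA` where undefined in either
#'   taxon).
#' @export
compute_gst_ret_max <- function(gm, panel, mask = NULL) {
  check_panel(panel, gm)
  f_ret <- allele_frequencies(gm, panel_samples(panel, "RET_REF"), mask)
  f_max <- allele_frequencies(gm, panel_samples(panel, "MAX_REF"), mask)
  data.frame(chrom = f_ret$chrom, pos = f_ret$pos,
             p_ret = f_ret$p_alt, p_max = f_max$p_alt,
             n_ret = f_ret$n_obs, n_max = f_max$n_obs,
             gst = nei_gst(f_ret$p_alt, f_max$p_alt),
             stringsAsFactors = FALSE)
}

#' Select the diagnostic-polymorphism panel
#'
#' Keeps loci with `gst >= threshold`; among indel records only anchor
#' (first) positions are retained to avoid redundant information. Each DP is
#' oriented by assigning the major allele of each taxon (from the masked
#' frequencies) as that taxon's diagnostic allele; loci where the two major
#' alleles coincide or where a taxon frequency sits exactly at 0.5 are
#' dropped with a warning, since they cannot orient a call.
#'
#' @param gst_table Output of [compute_gst_ret_max()].
#' @param gm The [genotype_matrix()] the table was computed from (for allele
#'   strings and variant classes).
#' @param threshold Selection threshold on G_ST (default 0.9, inclusive).
#' @return A `diagnostic_panel` data frame `chrom pos ret_allele max_allele
#'   ret_is_alt gst class`, sorted by (chrom, pos).
#' @export
select_diagnostic_panel <- function(gst_table, gm, threshold = 0.9) {
  if (nrow(gst_table) != nrow(gm$loci))
    stop("`gst_table` does not cover the genotype matrix loci")
  loci <- gm$loci
  keep <- !is.na(gst_table$gst) & gst_table$gst >= threshold
  keep <- keep & (loci$class != "INDEL" | loci$indel_anchor)
  if (!any(keep))
    stop("no locus reaches G_ST >= ", threshold,
         "; review the threshold or the reference panels")
  sel <- gst_table[keep, , drop = FALSE]
  lsel <- loci[keep, , drop = FALSE]
  ret_is_alt <- sel$p_ret > 0.5
  max_is_alt <- sel$p_max > 0.5
  orientable <- sel$p_ret != 0.5 & sel$p_max != 0.5 & ret_is_alt != max_is_alt
  if (any(!orientable))
    warning(sum(!orientable), " locus/loci dropped: taxon major alleles ",
            "coincide or are undefined at ",
            paste(utils::head(paste(sel$chrom[!orientable],
                                    sel$pos[!orientable], sep = ":"), 5),
                  collapse = ", "))
  sel <- sel[orientable, , drop = FALSE]
  lsel <- lsel[orientable, , drop = FALSE]
  ret_is_alt <- ret_is_alt[orientable]
  if (!nrow(sel))
    stop("no orientable locus at G_ST >= ", threshold)
  out <- data.frame(
    chrom = sel$chrom, pos = sel$pos,
    ret_allele = ifelse(ret_is_alt, lsel$alt, lsel$ref),
    max_allele = ifelse(ret_is_alt, lsel$ref, lsel$alt),
    ret_is_alt = ret_is_alt,
    gst = sel$gst, class = lsel$class,
    stringsAsFactors = FALSE
  )
  out <- out[order_loci(out), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_panel", "data.frame")
  out
}

#' Read or write a diagnostic panel
#'
#' TSV `chrom pos ret_allele max_allele ret_is_alt gst class`.
#'
#' @param path File path.
#' @param dps A `diagnostic_panel`.
#' @return `read_diagnostic_panel()` returns the panel data frame.
#' @export
read_diagnostic_panel <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$chrom <- as.character(tab$chrom)
  class(tab) <- c("diagnostic_panel", "data.frame")
  tab
}

#' @rdname read_diagnostic_panel
#' @export
write_diagnostic_panel <- function(dps, path) {
  utils::write.table(as.data.frame(dps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
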