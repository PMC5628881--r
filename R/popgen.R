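# Estimators underlying diagnostic-polymorphism discovery: allele
# frequencies, observed/expected heterozygosity, Wright's fixation index,
# Nei's G_ST with equal-weight pooling of the two taxa, genotype
# dissimilarities and centroid similarity.

#' Per-locus allele frequencies of a sample subset
#'
#' Computes the alt-allele frequency from non-missing calls. Calls covered by
#' a mask (see [apply_mask()]) are treated as missing. Loci with no
#' contributing call are flagged undefined (`p_alt = NA`, `n_obs = 0`), never
#' raised as errors.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Sample ids to pool (default all).
#' @param mask Optional mask set (`sample chrom start end` data frame).
#' @return Data frame `chrom pos p_alt n_obs`, one row per locus.
#' @export
allele_frequencies <- function(gm, samples = gm$samples, mask = NULL) {
  if (!length(samples)) stop("`samples` must be nonempty")
  sub <- subset_samples(gm, samples)
  if (!is.null(mask)) {
    mask <- mask[mask$sample %in% samples, , drop = FALSE]
    sub <- apply_mask(sub, mask)
  }
  d <- sub$dosage
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
             p_alt = unname(p), n_obs = unname(n_obs),
             stringsAsFactors = FALSE)
}

#' Per-locus diversity statistics
#'
#' Observed heterozygosity `Ho` (heterozygote fraction among non-missing
#' calls), expected heterozygosity `He = 1 - sum(p_i^2)`, and Wright's
#' fixation index `Fw = 1 - Ho/He` (negative under heterozygote excess).
#' `Fw` is undefined (`NA`) at monomorphic loci (`He = 0`); all statistics
#' are undefined at loci with no non-missing call.
#'
#' @inheritParams allele_frequencies
#' @return Data frame `chrom pos n_obs Ho He Fw`.
#' @export
locus_diversity <- function(gm, samples = gm$samples) {
  if (!length(samples)) stop("`samples` must be nonempty")
  d <- subset_samples(gm, samples)$dosage
  n_obs <- colSums(!is.na(d))
  ho <- colSums(d == 1L, na.rm = TRUE) / n_obs
  p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  he <- 2 * p * (1 - p)                      # 1 - p^2 - q^2 for two alleles
  fw <- ifelse(he > 0, 1 - ho / he, NA_real_)
  ho[n_obs == 0] <- NA_real_
  he[n_obs == 0] <- NA_real_
  data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
             n_obs = unname(n_obs), Ho = unname(ho), He = unname(he),
             Fw = unname(fw), stringsAsFactors = FALSE)
}

#' Individual heterozygosity
#'
#' Fraction of non-missing calls of one sample that are heterozygous,
#' optionally over a locus subset.
#'
#' @param gm A [genotype_matrix()].
#' @param sample A sample id.
#' @param loci Optional logical or integer index over loci.
#' @return A fraction in \[0, 1\], or `NA` if no non-missing call.
#' @export
sample_heterozygosity <- function(gm, sample, loci = NULL) {
  if (!sample %in% gm$samples) stop("unknown sample: ", sample)
  x <- gm$dosage[sample, ]
  if (!is.null(loci)) x <- x[loci]
  if (all(is.na(x))) return(NA_real_)
  mean(x == 1L, na.rm = TRUE)
}

#' Nei's inter-population differentiation G_ST for two taxa
#'
#' Pools the two taxa with equal weight regardless of sample size:
#' `p_tot = (p_a + p_b) / 2`, `G_ST = (He_tot - (He_a + He_b)/2) / He_tot`.
#' `G_ST = 1` means fixed alternative alleles; 0 means identical
#' frequencies. Undefined (`NA`) when either frequency is undefined or the
#' pooled locus is monomorphic (`He_tot = 0`). Values are clamped to
#' \[0, 1\] within numerical tolerance 1e-12.
#'
#' @param p_a,p_b Alt-allele frequency vectors of the two taxa (`NA` where
#'   undefined).
#' @return Numeric vector of per-locus G_ST.
#' @export
nei_gst <- function(p_a, p_b) {
  het <- function(p) 2 * p * (1 - p)
  p_tot <- (p_a + p_b) / 2
  he_tot <- het(p_tot)
  g <- (he_tot - (het(p_a) + het(p_b)) / 2) / he_tot
  g[is.na(p_a) | is.na(p_b) | (!is.na(he_tot) & he_tot == 0)] <- NA_real_
  bad <- !is.na(g) & (g < -1e-12 | g > 1 + 1e-12)
  if (any(bad)) stop("G_ST outside [0,1] beyond numerical tolerance")
  pmin(pmax(g, 0), 1)
}

# number of matching alleles between two unordered diploid genotypes, from
# dosages: identical -> 2, one shared allele -> 1, disjoint -> 0
matching_alleles <- function(x_i, x_j) 2L - abs(x_i - x_j)

#' Pairwise genotype dissimilarities
#'
#' `simple_matching_dissimilarity()` is `d = 1 - mean(m_l / 2)` where `m_l`
#' counts matching alleles at locus `l` (2 identical genotypes, 1 one shared
#' allele, 0 none); `euclidean_dissimilarity()` is the square root of the
#' summed squared alt-dosage differences. Both use pairwise-complete loci
#' only and return `NA` when no locus is pairwise complete.
#'
#' @param gm A [genotype_matrix()].
#' @param i,j Sample ids.
#' @return A single dissimilarity value.
#' @export
simple_matching_dissimilarity <- function(gm, i, j) {
  x <- gm$dosage[i, ]; y <- gm$dosage[j, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  1 - mean(matching_alleles(x[ok], y[ok]) / 2)
}

#' @rdname simple_matching_dissimilarity
#' @export
euclidean_dissimilarity <- function(gm, i, j) {
  x <- gm$dosage[i, ]; y <- gm$dosage[j, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  sqrt(sum((x[ok] - y[ok])^2))
}

#' Full sample-by-sample dissimilarity matrix
#'
#' @param gm A [genotype_matrix()].
#' @param metric `"euclidean"` or `"simple_matching"`.
#' @return A `dissim_matrix`: list with symmetric matrix `d` (diagonal 0),
#'   matrix `L` of pairwise-complete locus counts, and `metric`.
#' @export
dissimilarity_matrix <- function(gm, metric = c("euclidean", "simple_matching")) {
  metric <- match.arg(metric)
  f <- if (metric == "euclidean") euclidean_dissimilarity
       else simple_matching_dissimilarity
  s <- gm$samples
  n <- length(s)
  d <- matrix(0, n, n, dimnames = list(s, s))
  L <- matrix(0L, n, n, dimnames = list(s, s))
  obs <- !is.na(gm$dosage)
  for (a in seq_len(n)) {
    L[a, a] <- sum(obs[a, ])
    if (a < n) for (b in seq(a + 1L, n)) {
      d[a, b] <- d[b, a] <- f(gm, s[a], s[b])
      L[a, b] <- L[b, a] <- sum(obs[a, ] & obs[b, ])
    }
  }
  structure(list(d = d, L = L, metric = metric), class = "dissim_matrix")
}

#' Export a dissimilarity matrix as square TSV
#'
#' Sample ids form the header row and first column, for consumption by
#' external tree-building or factorial-analysis tools.
#'
#' @param dm A `dissim_matrix` (or bare square matrix).
#' @param path Output file path.
#' @export
write_dissimilarity_matrix <- function(dm, path) {
  m <- if (inherits(dm, "dissim_matrix")) dm$d else dm
  tab <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele-frequency centroid of a reference set
#'
#' The per-locus allele-frequency profile of a reference subset,
#' mask-aware; identical to [allele_frequencies()] on the same inputs and
#' kept as its own operation because it is the object queries and reference
#' accessions are compared against.
#'
#' @param gm A [genotype_matrix()].
#' @param refs Reference sample ids.
#' @param mask Optional mask set.
#' @return Data frame `chrom pos p_alt n_obs`.
#' @export
taxon_centroid <- function(gm, refs, mask = NULL) {
  if (!length(refs)) stop("`refs` must be nonempty")
  allele_frequencies(gm, refs, mask)
}

#' Per-locus similarity of a sample to a centroid
#'
#' For a genotype carrying alleles a and b, `S = (p_c(a) + p_c(b)) / 2`
#' under the centroid frequencies: the expected per-allele matching rate,
#' the frequency-weighted generalization of the simple-matching index
#' (`S = 1 - d` when the centroid is a single genotype). Missing calls and
#' centroid-undefined loci yield `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param sample A sample id.
#' @param centroid A centroid profile from [taxon_centroid()].
#' @param loci Optional logical or integer index over loci.
#' @return Numeric vector of per-locus similarities.
#' @export
similarity_to_centroid <- function(gm, sample, centroid, loci = NULL) {
  if (nrow(centroid) != nrow(gm$loci))
    stop("centroid does not cover the genotype matrix loci")
  x <- gm$dosage[sample, ]
  p <- centroid$p_alt
  s <- (x * p + (2 - x) * (1 - p)) / 2
  if (!is.null(loci)) s <- s[loci]
  unname(s)
}

#' Per-locus statistics table
#'
#' Ho/He/Fw over all samples plus inter-taxon G_ST from the reference
#' panels; the per-locus export of the discovery stage.
#'
#' @param gm A [genotype_matrix()].
#' @param panel Sample panel data frame.
#' @param mask Optional mask set applied to the reference frequencies.
#' @return Data frame `chrom pos Ho He Fw GST`.
#' @export
locus_stats_table <- function(gm, panel, mask = NULL) {
  div <- locus_diversity(gm)
  f_ret <- allele_frequencies(gm, panel_samples(panel, "RET_REF"), mask)
  f_max <- allele_frequencies(gm, panel_samples(panel, "MAX_REF"), mask)
  data.frame(chrom = div$chrom, pos = div$pos, Ho = div$Ho, He = div$He,
             Fw = div$Fw, GST = nei_gst(f_ret$p_alt, f_max$p_alt),
             stringsAsFactors = FALSE)
}

#' @rdname locus_stats_table
#' @param stats The table returned by `locus_stats_table()`.
#' @param path Output file path.
#' @export
write_locus_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
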