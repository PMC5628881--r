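# Call-level and locus-level quality filters applied ahead of any
# population-genetic estimation. All filters are idempotent and never alter
# the values of surviving calls.

#' Construct a read-depth matrix
#'
#' @param reads Non-negative integer matrix of per-call read counts with the
#'   same dimensions (and sample rownames) as the genotype matrix it
#'   accompanies.
#' @param gm The matching [genotype_matrix()].
#' @return An object of class `depth_matrix`.
#' @export
depth_matrix <- function(reads, gm) {
  if (!is.matrix(reads)) stop("`reads` must be a matrix")
  if (!identical(dim(reads), dim(gm$dosage)))
    stop("depth matrix dimensions do not match the genotype matrix")
  if (any(reads < 0, na.rm = TRUE)) stop("read counts must be >= 0")
  dimnames(reads) <- dimnames(gm$dosage)
  structure(list(reads = reads), class = "depth_matrix")
}

#' Mask low-depth calls
#'
#' Calls supported by fewer than `min_reads` reads are unreliable and are
#' replaced by missing data; calls at exactly `min_reads` are kept. Cells
#' with an unknown (`NA`) read count are treated as below threshold.
#'
#' @param gm A [genotype_matrix()].
#' @param dm The matching [depth_matrix()].
#' @param min_reads Minimum reads per call (default 5).
#' @return A `genotype_matrix` with low-depth calls set missing.
#' @export
apply_depth_threshold <- function(gm, dm, min_reads = 5L) {
  if (!inherits(dm, "depth_matrix")) stop("`dm` must be a depth_matrix")
  if (!identical(dim(dm$reads), dim(gm$dosage)))
    stop("depth matrix dimensions do not match the genotype matrix")
  d <- gm$dosage
  low <- is.na(dm$reads) | dm$reads < min_reads
  d[low] <- NA_integer_
  genotype_matrix(d, gm$loci)
}

locus_missing_rate <- function(dosage) colMeans(is.na(dosage))

locus_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2     # alt-allele frequency
  pmin(p, 1 - p)                              # NaN when all missing
}

#' Filter loci on missingness and minor allele frequency
#'
#' Drops loci whose missing fraction over all samples exceeds `max_missing`
#' or whose minor allele frequency (from non-missing dosages over all
#' samples) is below `min_maf`; the MAF boundary itself is retained. A locus
#' with every call missing is removed by the missingness rule.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.5).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @return The filtered `genotype_matrix`, locus order preserved.
#' @export
filter_loci <- function(gm, max_missing = 0.5, min_maf = 0.05) {
  if (!nrow(gm$loci)) stop("empty genotype matrix")
  miss <- locus_missing_rate(gm$dosage)
  maf <- locus_maf(gm$dosage)
  keep <- miss <= max_missing & !is.nan(maf) & maf >= min_maf
  subset_loci(gm, keep)
}

#' Filter loci on reference-panel missingness
#'
#' Keeps loci whose missing fraction among the reference accessions
#' (RET_REF and MAX_REF roles combined) is strictly below `max_ref_missing`.
#' Query samples are not consulted.
#'
#' @param gm A [genotype_matrix()].
#' @param panel Sample panel data frame (`sample`, `role`).
#' @param max_ref_missing Missing-fraction bound among references
#'   (default 0.3, exclusive).
#' @return The filtered `genotype_matrix`.
#' @export
filter_by_reference_missing <- function(gm, panel, max_ref_missing = 0.3) {
  refs <- panel_samples(panel, c("RET_REF", "MAX_REF"))
  if (!length(refs)) stop("panel contains no reference samples")
  absent <- setdiff(refs, gm$samples)
  if (length(absent))
    stop("reference sample(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  miss <- locus_missing_rate(gm$dosage[refs, , drop = FALSE])
  subset_loci(gm, miss < max_ref_missing)
}
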