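# Core container: samples x biallelic loci, alt-allele dosage coding.
# Dosage 0 = ref/ref, 1 = ref/alt (unordered het), 2 = alt/alt, NA = missing.

#' Construct a genotype matrix
#'
#' The central container of the pipeline: an unordered diploid call matrix
#' over biallelic loci, stored as alt-allele dosage (0, 1, 2 or `NA` for
#' missing). No phasing is assumed anywhere.
#'
#' @param dosage Integer matrix, samples in rows (rownames required), loci in
#'   columns. Values must be 0, 1, 2 or `NA`.
#' @param loci Data frame with one row per column of `dosage` and columns
#'   `chrom` (character), `pos` (1-based bp coordinate), `ref`, `alt`
#'   (allele strings), `class` (`"SNP"` or `"INDEL"`), `indel_anchor`
#'   (logical; `TRUE` for the first position of a multi-position indel
#'   record, `FALSE` for SNPs and indel continuation positions).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `loci` and `dosage`, loci sorted by (chrom, pos).
#' @export
genotype_matrix <- function(dosage, loci) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  if (is.null(rownames(dosage))) stop("`dosage` must have sample rownames")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample identifiers in `dosage`")
  loci <- as.data.frame(loci)
  needed <- c("chrom", "pos", "ref", "alt", "class", "indel_anchor")
  miss <- setdiff(needed, names(loci))
  if (length(miss)) stop("`loci` lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(loci) != ncol(dosage))
    stop("`loci` rows (", nrow(loci), ") != dosage columns (", ncol(dosage), ")")
  if (any(loci$pos < 1)) stop("locus positions must be >= 1")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  key <- paste(loci$chrom, loci$pos, sep = ":")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate locus (chrom, pos): ", dup)
  }
  ord <- order_loci(loci)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- paste(loci$chrom, loci$pos, sep = ":")
  structure(
    list(samples = rownames(dosage), loci = loci, dosage = dosage),
    class = "genotype_matrix"
  )
}

# chromosome labels sort numerically when they all parse as numbers
order_loci <- function(loci) {
  num <- suppressWarnings(as.numeric(loci$chrom))
  if (anyNA(num)) order(loci$chrom, loci$pos) else order(num, loci$pos)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$loci), " loci (", length(unique(x$loci$chrom)),
      " chromosomes, ", sprintf("%.1f%%", 100 * miss), " missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Accessors for a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @return `geno_samples()` the sample identifiers; `geno_loci()` the locus
#'   metadata data frame; `geno_dosage()` the integer dosage matrix.
#' @export
geno_samples <- function(gm) gm$samples

#' @rdname geno_samples
#' @export
geno_loci <- function(gm) gm$loci

#' @rdname geno_samples
#' @export
geno_dosage <- function(gm) gm$dosage

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param keep Logical or integer index over loci (`subset_loci`) or a
#'   character vector of sample ids (`subset_samples`).
#' @return A `genotype_matrix` restricted to the requested loci or samples.
#' @export
subset_loci <- function(gm, keep) {
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$loci[keep, , drop = FALSE])
}

#' @rdname subset_loci
#' @export
subset_samples <- function(gm, keep) {
  absent <- setdiff(keep, gm$samples)
  if (length(absent))
    stop("unknown sample(s): ", paste(absent, collapse = ", "))
  genotype_matrix(gm$dosage[keep, , drop = FALSE], gm$loci)
}

#' Stack two genotype matrices sample-wise
#'
#' Both matrices must describe the identical locus set; used to combine
#' reference panels with query varieties.
#'
#' @param gm_a,gm_b `genotype_matrix` objects over the same loci.
#' @return A `genotype_matrix` with the samples of both inputs.
#' @export
bind_samples <- function(gm_a, gm_b) {
  if (!identical(gm_a$loci$chrom, gm_b$loci$chrom) ||
      !identical(gm_a$loci$pos, gm_b$loci$pos))
    stop("genotype matrices do not share the same loci")
  genotype_matrix(rbind(gm_a$dosage, gm_b$dosage), gm_a$loci)
}
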