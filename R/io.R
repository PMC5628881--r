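# Readers/writers for the genotype TSV dialect, VCF, sample panels and the
# tabular exports consumed by downstream tools.

#' Read a genotype table (TSV dialect or VCF)
#'
#' The TSV dialect has header columns `chrom pos ref alt class` followed by
#' one column per sample holding alt-allele dosages in `{0, 1, 2, NA}`.
#' `class` takes `SNP`, `INDEL` (the anchor, i.e. first position of an indel
#' record) or `INDEL_BODY` (a non-anchor continuation position of a
#' multi-position indel record).
#'
#' VCF input (4.x) uses the GT FORMAT field; records must be biallelic —
#' multi-allelic records are dropped with a warning naming them. Records
#' whose REF or ALT spans more than one base are classed INDEL with
#' `indel_anchor = TRUE` (a VCF indel is a single record at its first
#' position).
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @param depth For VCF only: if `TRUE` and the file carries a DP FORMAT
#'   field, return `list(genotypes = , depth = )` instead of the bare matrix.
#' @return A [genotype_matrix()] (or a list, see `depth`).
#' @export
read_genotype_table <- function(path, format = c("tsv", "vcf"), depth = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_genotype_tsv(path) else read_genotype_vcf(path, depth)
}

read_genotype_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "class")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("TSV genotype table lacks columns: ", paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(tab), needed)
  if (!length(sample_cols)) stop("TSV genotype table has no sample columns")
  multi <- grepl(",", tab$alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) rejected: ",
            paste(utils::head(paste(tab$chrom[multi], tab$pos[multi], sep = ":"), 5),
                  collapse = ", "))
    tab <- tab[!multi, , drop = FALSE]
  }
  bad_class <- !tab$class %in% c("SNP", "INDEL", "INDEL_BODY")
  if (any(bad_class))
    stop("malformed record at line ", which(bad_class)[1] + 1L,
         ": unknown class '", tab$class[bad_class][1], "'")
  pos <- suppressWarnings(as.integer(tab$pos))
  if (anyNA(pos))
    stop("malformed record at line ", which(is.na(pos))[1] + 1L,
         ": non-integer pos")
  raw <- as.matrix(tab[, sample_cols, drop = FALSE])
  raw[raw %in% c("NA", ".", "")] <- NA
  bad <- !(raw %in% c("0", "1", "2") | is.na(raw))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed record at line ", idx[1] + 1L,
         ": dosage '", raw[bad][1], "' not in {0,1,2,NA}")
  }
  dosage <- t(matrix(as.integer(raw), nrow = nrow(tab),
                     dimnames = list(NULL, sample_cols)))
  rownames(dosage) <- sample_cols
  loci <- data.frame(
    chrom = tab$chrom, pos = pos, ref = tab$ref, alt = tab$alt,
    class = ifelse(tab$class == "SNP", "SNP", "INDEL"),
    indel_anchor = tab$class == "INDEL",
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosage, loci)
}

read_genotype_vcf <- function(path, depth = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) rejected: ",
            paste(utils::head(paste(fix$CHROM[multi], fix$POS[multi], sep = ":"), 5),
                  collapse = ", "))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")        # loci x samples
  alt1 <- substr(gt, 1, 1)
  alt2 <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.integer(alt1) + as.integer(alt2))
  dos[alt1 == "." | alt2 == "."] <- NA
  dosage <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  dosage <- t(dosage)                              # samples x loci
  is_indel <- nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  loci <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    class = ifelse(is_indel, "INDEL", "SNP"),
    indel_anchor = is_indel,
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(dosage, loci)
  if (!depth) return(gm)
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(dp)) return(gm)
  dp <- t(dp)
  dp <- dp[gm$samples, , drop = FALSE]
  # re-sort depth columns to the (chrom, pos) order of the genotype matrix
  ord <- match(colnames(gm$dosage), paste(fix$CHROM, fix$POS, sep = ":"))
  dp <- dp[, ord, drop = FALSE]
  colnames(dp) <- colnames(gm$dosage)
  list(genotypes = gm, depth = depth_matrix(dp, gm))
}

#' Write a genotype matrix in the TSV dialect
#'
#' Round-trips exactly through [read_genotype_table()].
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @export
write_genotype_table <- function(gm, path) {
  loci <- gm$loci
  class_col <- ifelse(loci$class == "SNP", "SNP",
                      ifelse(loci$indel_anchor, "INDEL", "INDEL_BODY"))
  tab <- data.frame(chrom = loci$chrom, pos = loci$pos, ref = loci$ref,
                    alt = loci$alt, class = class_col,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(t(gm$dosage), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a genotype matrix as minimal VCF 4.2
#'
#' Emits GT calls (unphased) and, when `depth` is supplied, per-call DP.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @param depth Optional [depth_matrix()] aligned to `gm`.
#' @export
write_vcf <- function(gm, path, depth = NULL) {
  gt_code <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  fmt <- "GT"
  if (!is.null(depth)) {
    gt <- matrix(paste0(gt, ":", depth$reads), nrow = nrow(d))
    fmt <- "GT:DP"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(depth))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  loci <- gm$loci
  body <- cbind(loci$chrom, loci$pos, ".", loci$ref, loci$alt, ".", ".", ".",
                fmt, t(gt))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a sample panel
#'
#' Two-column TSV `sample role` with roles in
#' `{RET_REF, MAX_REF, QUERY}` assigning each sample to the first reference
#' taxon (e.g. mandarins), the second (e.g. pummelos), or the queries.
#'
#' @param path File path.
#' @return A data frame with columns `sample` and `role`.
#' @export
read_sample_panel <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample", "role") %in% names(tab)))
    stop("panel file needs columns `sample` and `role`")
  bad <- !tab$role %in% c("RET_REF", "MAX_REF", "QUERY")
  if (any(bad)) stop("unknown role(s): ", paste(unique(tab$role[bad]), collapse = ", "))
  tab[c("sample", "role")]
}

#' @rdname read_sample_panel
#' @param panel Data frame with columns `sample`, `role`.
#' @export
write_sample_panel <- function(panel, path) {
  utils::write.table(panel[c("sample", "role")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

panel_samples <- function(panel, roles) panel$sample[panel$role %in% roles]

check_panel <- function(panel, gm, min_refs = 2L) {
  absent <- setdiff(panel$sample, gm$samples)
  if (length(absent))
    stop("panel sample(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  n_ret <- sum(panel$role == "RET_REF")
  n_max <- sum(panel$role == "MAX_REF")
  if (n_ret < min_refs || n_max < min_refs)
    stop("need >= ", min_refs, " RET_REF and MAX_REF samples (have ",
         n_ret, " + ", n_max, ")")
  invisible(TRUE)
}
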