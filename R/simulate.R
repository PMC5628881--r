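# Synthetic data with full ground truth: a two-taxon ancestral model
# (mixture of fixed differences and shared polymorphisms), reference panels
# with optional planted introgressions, and admixed query genomes built as
# per-homolog ancestry block mosaics. Defaults emulate the study regime:
# 9 chromosomes, ~39,000 loci, 11 + 6 references, 12.6% missing data, and a
# fixed/shared mixture whose mean inter-taxon G_ST is ~0.47.

#' Simulate a two-taxon ancestral allele-frequency model
#'
#' A fraction `prop_fixed` of loci carries fixed alternative alleles between
#' the taxa (true `G_ST = 1`), uniformly interleaved with shared
#' polymorphisms whose per-taxon alt-allele frequencies are drawn from a
#' symmetric `Beta(beta_shape, beta_shape)`. With `shared_mode =
#' "independent"` the two taxa draw independently (differentiated gene
#' pools); `"identical"` gives both taxa the same frequency (no
#' differentiation outside the fixed loci). The defaults
#' (`prop_fixed = 0.2`, `beta_shape = 0.3`) give a mean true G_ST of ~0.47.
#'
#' @param n_chrom Number of chromosomes (default 9).
#' @param loci_per_chrom Loci per chromosome (default 4333, ~39k genome-wide).
#' @param chrom_length Chromosome length in bp (default 33 Mb).
#' @param prop_fixed Fraction of fixed-difference loci.
#' @param beta_shape Shape of the symmetric Beta law for shared loci.
#' @param prop_indel Fraction of loci simulated as indel records (anchors).
#' @param shared_mode `"independent"` or `"identical"` taxon draws.
#' @param seed Optional integer seed.
#' @return An `ancestral_model`: list with `loci` (locus metadata plus true
#'   `p_ret`, `p_max`, `fixed`) and `chrom_lengths`.
#' @export
simulate_ancestral_model <- function(n_chrom = 9L, loci_per_chrom = 4333L,
                                     chrom_length = 3.3e7,
                                     prop_fixed = 0.2, beta_shape = 0.3,
                                     prop_indel = 0.22,
                                     shared_mode = c("independent", "identical"),
                                     seed = NULL) {
  shared_mode <- match.arg(shared_mode)
  if (prop_fixed < 0 || prop_fixed > 1) stop("`prop_fixed` must be in [0, 1]")
  if (prop_indel < 0 || prop_indel > 1) stop("`prop_indel` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  loci <- lapply(seq_len(n_chrom), function(ch) {
    n <- loci_per_chrom
    pos <- sort(sample.int(chrom_length, n))
    n_fixed <- round(prop_fixed * n)
    fixed <- rep(FALSE, n)
    fixed[sample.int(n, n_fixed)] <- TRUE
    p_ret <- p_max <- numeric(n)
    flip <- stats::runif(n_fixed) < 0.5
    p_ret[fixed] <- as.numeric(flip)
    p_max[fixed] <- as.numeric(!flip)
    n_shared <- n - n_fixed
    p_ret[!fixed] <- stats::rbeta(n_shared, beta_shape, beta_shape)
    p_max[!fixed] <- if (shared_mode == "identical") p_ret[!fixed]
                     else stats::rbeta(n_shared, beta_shape, beta_shape)
    is_indel <- stats::runif(n) < prop_indel
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    alt[is_indel] <- paste0(ref[is_indel], alt[is_indel])   # insertions
    data.frame(chrom = as.character(ch), pos = pos, ref = ref, alt = alt,
               class = ifelse(is_indel, "INDEL", "SNP"),
               indel_anchor = is_indel,
               p_ret = p_ret, p_max = p_max, fixed = fixed,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  structure(list(loci = loci,
                 chrom_lengths = stats::setNames(rep(chrom_length, n_chrom),
                                                 as.character(seq_len(n_chrom)))),
            class = "ancestral_model")
}

#' @export
print.ancestral_model <- function(x, ...) {
  cat("ancestral_model: ", nrow(x$loci), " loci on ",
      length(x$chrom_lengths), " chromosomes (",
      sum(x$loci$fixed), " fixed differences)\n", sep = "")
  invisible(x)
}

# ---- ancestry specifications -------------------------------------------

new_ancestry_spec <- function(blocks, pedigree = "BLOCKS") {
  blocks <- blocks[order(suppressWarnings(as.numeric(blocks$chrom)),
                         blocks$chrom, blocks$homolog, blocks$start), ,
                   drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, pedigree = pedigree),
            class = "ancestry_spec")
}

#' Ancestry specifications for synthetic genomes
#'
#' An ancestry spec assigns every bp of both homologs of every chromosome to
#' one of the two ancestral taxa; it is the ground truth that painted
#' karyotypes and admixture proportions are scored against.
#'
#' * `spec_pure()` — both homologs entirely of one taxon.
#' * `spec_f1()` — one full RET homolog plus one full MAX homolog.
#' * `spec_bc()` — `n` successive backcrosses of an F1 onto the recurrent
#'   taxon, each meiosis placing one uniform-random crossover per
#'   chromosome; the expected residual donor fraction is `0.5^(n+1)`.
#' * `spec_blocks()` — explicit blocks (data frame `chrom homolog start end
#'   taxon`) that must tile both homologs of every chromosome exactly.
#'
#' @param model An `ancestral_model` (supplies chromosome lengths).
#' @param taxon,recurrent `"RET"` or `"MAX"`.
#' @param n Number of backcross generations.
#' @param blocks Explicit block table.
#' @param seed Optional integer seed (for `spec_bc`'s crossovers).
#' @return An `ancestry_spec`: list with `blocks` and `pedigree`.
#' @export
spec_pure <- function(model, taxon = c("RET", "MAX")) {
  taxon <- match.arg(taxon)
  new_ancestry_spec(whole_genome_blocks(model, taxon, taxon),
                    paste0("PURE_", taxon))
}

#' @rdname spec_pure
#' @export
spec_f1 <- function(model) {
  new_ancestry_spec(whole_genome_blocks(model, "RET", "MAX"), "F1")
}

whole_genome_blocks <- function(model, taxon_h1, taxon_h2) {
  ch <- names(model$chrom_lengths)
  data.frame(chrom = rep(ch, each = 2),
             homolog = rep(1:2, length(ch)),
             start = 1L,
             end = rep(unname(model$chrom_lengths), each = 2),
             taxon = rep(c(taxon_h1, taxon_h2), length(ch)),
             stringsAsFactors = FALSE)
}

#' @rdname spec_pure
#' @export
spec_blocks <- function(model, blocks) {
  needed <- c("chrom", "homolog", "start", "end", "taxon")
  if (!all(needed %in% names(blocks)))
    stop("`blocks` needs columns ", paste(needed, collapse = " "))
  if (!all(blocks$taxon %in% c("RET", "MAX")))
    stop("block taxa must be RET or MAX")
  spec <- new_ancestry_spec(blocks)
  validate_spec(model, spec)
  spec
}

validate_spec <- function(model, spec) {
  b <- spec$blocks
  for (ch in names(model$chrom_lengths)) {
    len <- model$chrom_lengths[[ch]]
    for (h in 1:2) {
      d <- b[b$chrom == ch & b$homolog == h, , drop = FALSE]
      if (!nrow(d))
        stop("spec does not cover chromosome ", ch, " homolog ", h)
      d <- d[order(d$start), , drop = FALSE]
      if (d$start[1] != 1 || d$end[nrow(d)] != len ||
          (nrow(d) > 1 && any(d$start[-1] != d$end[-nrow(d)] + 1)))
        stop("blocks do not tile chromosome ", ch, " homolog ", h,
             " (1..", len, ")")
      if (any(d$end > len)) stop("block outside chromosome ", ch, " bounds")
    }
  }
  invisible(TRUE)
}

# one meiosis: a gamete from two homologs with exactly one crossover at a
# uniform-random bp, random leading homolog
gamete_blocks <- function(h1, h2, len) {
  x <- floor(stats::runif(1, min = 1, max = len))   # crossover after bp x
  pair <- if (stats::runif(1) < 0.5) list(h1, h2) else list(h2, h1)
  left <- clip_blocks(pair[[1]], 1, x)
  right <- clip_blocks(pair[[2]], x + 1, len)
  simplify_blocks(rbind(left, right))
}

clip_blocks <- function(b, lo, hi) {
  b <- b[b$end >= lo & b$start <= hi, , drop = FALSE]
  b$start <- pmax(b$start, lo)
  b$end <- pmin(b$end, hi)
  b
}

simplify_blocks <- function(b) {
  b <- b[order(b$start), , drop = FALSE]
  keep <- c(TRUE, b$taxon[-1] != b$taxon[-nrow(b)])
  grp <- cumsum(keep)
  data.frame(start = tapply(b$start, grp, min),
             end = tapply(b$end, grp, max),
             taxon = b$taxon[keep],
             stringsAsFactors = FALSE)
}

#' @rdname spec_pure
#' @export
spec_bc <- function(model, n, recurrent = c("RET", "MAX"), seed = NULL) {
  recurrent <- match.arg(recurrent)
  if (n < 1) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  donor <- if (recurrent == "RET") "MAX" else "RET"
  blocks <- lapply(names(model$chrom_lengths), function(ch) {
    len <- model$chrom_lengths[[ch]]
    h1 <- data.frame(start = 1, end = len, taxon = "RET",
                     stringsAsFactors = FALSE)
    h2 <- data.frame(start = 1, end = len, taxon = "MAX",
                     stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      g <- gamete_blocks(h1, h2, len)
      h1 <- g
      h2 <- data.frame(start = 1, end = len, taxon = recurrent,
                       stringsAsFactors = FALSE)
    }
    rbind(cbind(chrom = ch, homolog = 1L, h1, stringsAsFactors = FALSE),
          cbind(chrom = ch, homolog = 2L, h2, stringsAsFactors = FALSE))
  })
  blocks <- do.call(rbind, blocks)
  new_ancestry_spec(blocks[c("chrom", "homolog", "start", "end", "taxon")],
                    paste0("BC(", n, ",", recurrent, ")"))
}

#' Expected MAX genome fraction of an ancestry spec
#'
#' MAX bp over both homologs divided by twice the genome length: the truth
#' value admixture estimates are compared against.
#'
#' @param spec An `ancestry_spec`.
#' @param model The `ancestral_model` it was built for.
#' @return A fraction in \[0, 1\].
#' @export
spec_prop_max <- function(spec, model) {
  b <- spec$blocks
  max_bp <- sum(as.numeric(b$end - b$start + 1) * (b$taxon == "MAX"))
  max_bp / (2 * sum(model$chrom_lengths))
}

# taxon of one homolog at given positions (blocks tile the chromosome)
taxon_at <- function(blocks, pos) {
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  blocks$taxon[findInterval(pos, blocks$start)]
}

# draw one diploid genome: per homolog, Bernoulli alt-allele draws from the
# block taxon's frequency (HWE within taxon, linkage equilibrium)
draw_genome <- function(model, spec) {
  loci <- model$loci
  dosage <- integer(nrow(loci))
  for (ch in names(model$chrom_lengths)) {
    idx <- which(loci$chrom == ch)
    pos <- loci$pos[idx]
    for (h in 1:2) {
      b <- spec$blocks[spec$blocks$chrom == ch & spec$blocks$homolog == h, ,
                       drop = FALSE]
      tax <- taxon_at(b, pos)
      p <- ifelse(tax == "RET", loci$p_ret[idx], loci$p_max[idx])
      dosage[idx] <- dosage[idx] + stats::rbinom(length(idx), 1L, p)
    }
  }
  dosage
}

#' Simulate a reference panel
#'
#' Draws `n_ret` + `n_max` reference accessions from the ancestral model
#' (HWE within taxon, linkage equilibrium across loci). Named entries of
#' `introgressions` replace the pure ancestry of that accession with an
#' explicit [spec_blocks()] layout, planting other-taxon blocks on one or
#' both homologs.
#'
#' @param model An `ancestral_model`.
#' @param n_ret,n_max Panel sizes (defaults 11 and 6).
#' @param introgressions Optional named list (`sample id -> ancestry_spec`).
#' @param seed Optional integer seed.
#' @return List with `genotypes` ([genotype_matrix()]), `panel` (sample
#'   panel data frame) and `truth` (named list of `ancestry_spec`).
#' @export
simulate_reference_panel <- function(model, n_ret = 11L, n_max = 6L,
                                     introgressions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- c(sprintf("RET_%02d", seq_len(n_ret)),
           sprintf("MAX_%02d", seq_len(n_max)))
  roles <- rep(c("RET_REF", "MAX_REF"), c(n_ret, n_max))
  taxa <- rep(c("RET", "MAX"), c(n_ret, n_max))
  unknown <- setdiff(names(introgressions), ids)
  if (length(unknown))
    stop("introgression spec(s) for unknown sample(s): ",
         paste(unknown, collapse = ", "))
  truth <- stats::setNames(lapply(seq_along(ids), function(k) {
    if (!is.null(introgressions[[ids[k]]])) introgressions[[ids[k]]]
    else spec_pure(model, taxa[k])
  }), ids)
  dosage <- t(vapply(ids, function(s) draw_genome(model, truth[[s]]),
                     integer(nrow(model$loci))))
  gm <- genotype_matrix(dosage, model$loci[c("chrom", "pos", "ref", "alt",
                                             "class", "indel_anchor")])
  list(genotypes = gm,
       panel = data.frame(sample = ids, role = roles,
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate an admixed query variety
#'
#' Draws one diploid genome whose per-homolog ancestry follows `spec`
#' (an F1, a BC(n) mosaic or explicit blocks).
#'
#' @param model An `ancestral_model`.
#' @param spec An `ancestry_spec`.
#' @param sample Sample identifier for the genotype row.
#' @param seed Optional integer seed.
#' @return List with `genotypes` (single-sample [genotype_matrix()]),
#'   `spec`, and `prop_max` (the true MAX genome fraction).
#' @export
simulate_admixed_variety <- function(model, spec, sample = "QUERY",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_spec(model, spec)
  dosage <- matrix(draw_genome(model, spec), nrow = 1,
                   dimnames = list(sample, NULL))
  gm <- genotype_matrix(dosage, model$loci[c("chrom", "pos", "ref", "alt",
                                             "class", "indel_anchor")])
  list(genotypes = gm, spec = spec, prop_max = spec_prop_max(spec, model))
}

#' Simulate several query varieties at once
#'
#' @param model An `ancestral_model`.
#' @param specs Named list of `ancestry_spec` (names become sample ids).
#' @param seed Optional integer seed.
#' @return List with `genotypes`, `truth` (the specs) and `prop_max`
#'   (named vector of true MAX fractions).
#' @export
simulate_queries <- function(model, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(specs)) || anyDuplicated(names(specs)))
    stop("`specs` must be a uniquely named list")
  dosage <- t(vapply(specs, function(sp) {
    validate_spec(model, sp)
    draw_genome(model, sp)
  }, integer(nrow(model$loci))))
  rownames(dosage) <- names(specs)
  gm <- genotype_matrix(dosage, model$loci[c("chrom", "pos", "ref", "alt",
                                             "class", "indel_anchor")])
  list(genotypes = gm, truth = specs,
       prop_max = vapply(specs, spec_prop_max, numeric(1), model = model))
}

#' Inject missing data (optionally with a matching depth matrix)
#'
#' Each call is independently set missing with probability `rate`. With
#' `depth = TRUE` a read-depth matrix is also returned in which exactly the
#' missing cells carry fewer than 5 reads, so that
#' [apply_depth_threshold()] reproduces the same missingness pattern.
#'
#' @param gm A [genotype_matrix()].
#' @param rate Missingness probability per call (default 0.126).
#' @param seed Optional integer seed.
#' @param depth If `TRUE`, also return a [depth_matrix()].
#' @return The masked `genotype_matrix`, or
#'   `list(genotypes = , depth = )` when `depth = TRUE`.
#' @export
inject_missingness <- function(gm, rate = 0.126, seed = NULL, depth = FALSE) {
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  d <- gm$dosage
  drop <- matrix(stats::runif(length(d)) < rate, nrow = nrow(d))
  d[drop] <- NA_integer_
  out <- genotype_matrix(d, gm$loci)
  if (!depth) return(out)
  reads <- matrix(5L + stats::rpois(length(d), 15), nrow = nrow(d))
  reads[drop] <- sample(0:4, sum(drop), replace = TRUE)
  list(genotypes = out, depth = depth_matrix(reads, out))
}

#' Expected window states implied by an ancestry spec
#'
#' For each karyotype window of `win` DPs (the same window grid as
#' [call_windows()]), the state implied by the ancestry of both homologs at
#' those positions. Windows straddling an ancestry breakpoint are labeled
#' `BOUNDARY` and are excluded from recovery scoring.
#'
#' @param spec An `ancestry_spec`.
#' @param dps A `diagnostic_panel`.
#' @param win Window size in DPs (default 20).
#' @return Data frame `chrom dp_start dp_end bp_start bp_end state` with
#'   `state` in `{RET/RET, MAX/MAX, RET/MAX, BOUNDARY}`.
#' @export
truth_windows <- function(spec, dps, win = 20L) {
  blocks <- dp_window_blocks(dps, win)
  state_per_dp <- character(nrow(dps))
  for (ch in unique(dps$chrom)) {
    idx <- which(dps$chrom == ch)
    pos <- dps$pos[idx]
    b1 <- spec$blocks[spec$blocks$chrom == ch & spec$blocks$homolog == 1, ,
                      drop = FALSE]
    b2 <- spec$blocks[spec$blocks$chrom == ch & spec$blocks$homolog == 2, ,
                      drop = FALSE]
    t1 <- taxon_at(b1, pos)
    t2 <- taxon_at(b2, pos)
    state_per_dp[idx] <- ifelse(t1 == "RET" & t2 == "RET", "RET/RET",
                         ifelse(t1 == "MAX" & t2 == "MAX", "MAX/MAX",
                                "RET/MAX"))
  }
  blocks$state <- vapply(seq_len(nrow(blocks)), function(k) {
    st <- unique(state_per_dp[blocks$dp_start[k]:blocks$dp_end[k]])
    if (length(st) == 1) st else "BOUNDARY"
  }, character(1))
  blocks
}
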