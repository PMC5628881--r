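# Detection and masking of interspecific introgressions in the reference
# accessions, from the joint heterozygosity / centroid-similarity window
# tracks. Intervals are 1-based inclusive bp coordinates.

#' Flag introgressed intervals in one reference accession
#'
#' A window is flagged when (a) its windowed heterozygosity exceeds
#' `ho_threshold` (heterozygous introgressions pair haplotypes of the two
#' taxa, doubling heterozygosity relative to the intraspecific level), or
#' (b) its similarity to the other-taxon centroid is at least its similarity
#' to its own taxon's centroid (capturing homozygous introgressions that are
#' not hyper-heterozygous). Flagged windows that overlap or touch are
#' unioned; each interval spans from the position of the first marker of its
#' first flagged window to the last marker of its last flagged window.
#' Windows with Ho in (0.30, `ho_threshold`] are intraspecific-ambiguous and
#' are only flagged through condition (b).
#'
#' @param ho_track Heterozygosity track of the accession
#'   ([heterozygosity_track()], 120/40 windows).
#' @param sim_track Similarity track ([similarity_tracks()], 60/20 windows).
#' @param own_taxon `"RET"` or `"MAX"`: the taxon the accession represents.
#' @param ho_threshold Heterozygosity trigger (default 0.40, exclusive).
#' @return Data frame `chrom start end` of flagged intervals (possibly
#'   zero rows — an empty mask is a valid result).
#' @export
detect_introgressions <- function(ho_track, sim_track,
                                  own_taxon = c("RET", "MAX"),
                                  ho_threshold = 0.40) {
  own_taxon <- match.arg(own_taxon)
  ho_hit <- !is.na(ho_track$value) & ho_track$value > ho_threshold
  own <- if (own_taxon == "RET") sim_track$s_ret else sim_track$s_max
  oth <- if (own_taxon == "RET") sim_track$s_max else sim_track$s_ret
  sim_hit <- !is.na(own) & !is.na(oth) & oth >= own
  flagged <- rbind(
    ho_track[ho_hit, c("chrom", "bp_start", "bp_end")],
    sim_track[sim_hit, c("chrom", "bp_start", "bp_end")]
  )
  merge_intervals(flagged)
}

# union of overlapping or touching [start, end] intervals, per chromosome
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(data.frame(chrom = character(), start = integer(),
                                   end = integer(), stringsAsFactors = FALSE))
  names(iv) <- c("chrom", "start", "end")
  out <- lapply(split(iv, iv$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    start <- d$start[1]; end <- d$end[1]
    res <- NULL
    for (k in seq_len(nrow(d))[-1]) {
      if (d$start[k] <= end + 1L) {
        end <- max(end, d$end[k])
      } else {
        res <- rbind(res, data.frame(start = start, end = end))
        start <- d$start[k]; end <- d$end[k]
      }
    }
    res <- rbind(res, data.frame(start = start, end = end))
    data.frame(chrom = d$chrom[1], res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scan all reference accessions for introgressions
#'
#' Computes first-pass reference centroids and G_ST on unmasked data, then
#' per reference accession the heterozygosity (win `ho_win`/`ho_step`) and
#' centroid-similarity (win `sim_win`/`sim_step`, loci with first-pass
#' `G_ST > informative_gst`) tracks, and flags introgressed intervals via
#' [detect_introgressions()]. Query samples are never scanned or masked.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param panel Sample panel data frame.
#' @param ho_threshold,informative_gst Detection thresholds.
#' @param ho_win,ho_step,sim_win,sim_step Window parameters.
#' @return A mask set: data frame `sample chrom start end` (zero rows when
#'   nothing is flagged), with the per-locus first-pass G_ST attached as
#'   attribute `"gst1"`.
#' @export
scan_reference_introgressions <- function(gm, panel, ho_threshold = 0.40,
                                          informative_gst = 0.5,
                                          ho_win = 120L, ho_step = 40L,
                                          sim_win = 60L, sim_step = 20L) {
  check_panel(panel, gm)
  ret_refs <- panel_samples(panel, "RET_REF")
  max_refs <- panel_samples(panel, "MAX_REF")
  cen_ret <- taxon_centroid(gm, ret_refs)
  cen_max <- taxon_centroid(gm, max_refs)
  gst1 <- nei_gst(cen_ret$p_alt, cen_max$p_alt)
  refs <- data.frame(sample = c(ret_refs, max_refs),
                     taxon = rep(c("RET", "MAX"),
                                 c(length(ret_refs), length(max_refs))),
                     stringsAsFactors = FALSE)
  masks <- lapply(seq_len(nrow(refs)), function(k) {
    s <- refs$sample[k]
    ho <- heterozygosity_track(gm, s, win = ho_win, step = ho_step)
    sim <- similarity_tracks(gm, s, cen_ret, cen_max, gst1,
                             win = sim_win, step = sim_step,
                             min_gst = informative_gst)
    iv <- detect_introgressions(ho, sim, refs$taxon[k], ho_threshold)
    if (nrow(iv)) cbind(sample = s, iv, stringsAsFactors = FALSE) else NULL
  })
  masks <- do.call(rbind, masks)
  if (is.null(masks))
    masks <- data.frame(sample = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  rownames(masks) <- NULL
  attr(masks, "gst1") <- gst1
  masks
}

#' Convert masked intervals to missing data
#'
#' Calls of a masked sample at loci whose position falls inside one of its
#' mask intervals become missing; every other cell is untouched. Masking is
#' monotone: adding intervals never restores a call.
#'
#' @param gm A [genotype_matrix()].
#' @param masks Mask set data frame `sample chrom start end` (1-based
#'   inclusive).
#' @return The masked `genotype_matrix`.
#' @export
apply_mask <- function(gm, masks) {
  if (is.null(masks) || !nrow(masks)) return(gm)
  absent <- setdiff(masks$sample, gm$samples)
  if (length(absent))
    stop("mask sample(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  bad_chrom <- setdiff(masks$chrom, gm$loci$chrom)
  if (length(bad_chrom))
    stop("mask interval on unknown chromosome: ",
         paste(bad_chrom, collapse = ", "))
  d <- gm$dosage
  for (k in seq_len(nrow(masks))) {
    hit <- gm$loci$chrom == masks$chrom[k] &
      gm$loci$pos >= masks$start[k] & gm$loci$pos <= masks$end[k]
    d[masks$sample[k], hit] <- NA_integer_
  }
  genotype_matrix(d, gm$loci)
}

#' Read or write a mask set
#'
#' BED-like TSV `sample chrom start end`; unlike BED, coordinates are
#' 1-based inclusive (the convention of every interval in this package).
#'
#' @param path File path.
#' @param masks Mask set data frame.
#' @return `read_mask_set()` returns the mask data frame.
#' @export
read_mask_set <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  if (!all(c("sample", "chrom", "start", "end") %in% names(tab)))
    stop("mask file needs columns sample chrom start end")
  tab
}

#' @rdname read_mask_set
#' @export
write_mask_set <- function(masks, path) {
  utils::write.table(masks[c("sample", "chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
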