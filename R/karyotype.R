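# Local-ancestry painting: orient genotype calls against the diagnostic
# panel, call 20-DP windows by the best/second-configuration rule, merge
# window runs into karyotype segments, and estimate genome-wide admixture.

# DP call codes
DP_MISSING <- 0L
DP_RET_HOM <- 1L
DP_MAX_HOM <- 2L
DP_HET <- 3L

dp_states <- c("MISSING", "RET_HOM", "MAX_HOM", "HET")

#' Orient genotype calls against the diagnostic panel
#'
#' Each sample x DP cell becomes `RET_HOM` (both alleles the RET diagnostic
#' allele), `MAX_HOM`, `HET` (one of each) or `MISSING`. A call carrying an
#' allele outside the panel's pair would also be scored missing; with
#' biallelic loci and a panel derived from the same matrix this cannot
#' arise, but external panels keep the conservative rule.
#'
#' @param gm A [genotype_matrix()].
#' @param dps A `diagnostic_panel` ([select_diagnostic_panel()]).
#' @return Integer matrix (samples x DPs; codes 0 missing, 1 RET_HOM,
#'   2 MAX_HOM, 3 HET) of class `dp_call_matrix`, with the panel attached as
#'   attribute `"panel"`.
#' @export
classify_dp_genotypes <- function(gm, dps) {
  key_gm <- paste(gm$loci$chrom, gm$loci$pos, sep = ":")
  key_dp <- paste(dps$chrom, dps$pos, sep = ":")
  idx <- match(key_dp, key_gm)
  if (anyNA(idx))
    stop("DP locus/loci absent from genotype matrix: ",
         paste(utils::head(key_dp[is.na(idx)], 5), collapse = ", "))
  d <- gm$dosage[, idx, drop = FALSE]
  # dosage counts alt alleles; flip where the RET diagnostic allele is ref
  ret_dosage <- sweep(d, 2, ifelse(dps$ret_is_alt, 0L, 2L), function(x, f)
    abs(x - f))
  calls <- matrix(DP_MISSING, nrow = nrow(d), ncol = ncol(d),
                  dimnames = list(gm$samples, key_dp))
  calls[!is.na(ret_dosage) & ret_dosage == 2L] <- DP_RET_HOM
  calls[!is.na(ret_dosage) & ret_dosage == 0L] <- DP_MAX_HOM
  calls[!is.na(ret_dosage) & ret_dosage == 1L] <- DP_HET
  structure(calls, panel = as.data.frame(dps), class = "dp_call_matrix")
}

# per-chromosome successive non-overlapping blocks of `win` DPs; a final
# partial block with >= win/2 DPs stands alone, smaller remainders merge
# into the previous block
dp_window_blocks <- function(dps, win = 20L) {
  spans <- lapply(split(seq_len(nrow(dps)), dps$chrom), function(idx) {
    idx <- idx[order(dps$pos[idx])]
    sp <- window_spans(length(idx), win, win)
    data.frame(chrom = dps$chrom[idx[1]],
               dp_start = idx[sp$start], dp_end = idx[sp$end],
               bp_start = dps$pos[idx[sp$start]],
               bp_end = dps$pos[idx[sp$end]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, spans)
  rownames(out) <- NULL
  out[order_loci(data.frame(chrom = out$chrom, pos = out$bp_start)), ,
      drop = FALSE]
}

#' Call ancestry states in successive DP windows
#'
#' DPs are analyzed per chromosome in successive non-overlapping windows of
#' `win` markers. In each window the three genotype configurations are
#' counted among scored (non-missing) DPs; the window is called for the best
#' configuration when the best-to-second count ratio is at least `ratio`
#' (unanimous windows, where the second count is zero, are called; a best
#' count tied with the second gives ratio 1 and stays undetermined). Windows
#' with fewer than `min_scored` scored DPs are undetermined.
#'
#' @param calls A `dp_call_matrix` ([classify_dp_genotypes()]) or one row
#'   of it.
#' @param dps The matching `diagnostic_panel`.
#' @param win Window size in DPs (default 20).
#' @param min_scored Minimum scored DPs to attempt a call (default 10).
#' @param ratio Best/second configuration-frequency ratio (default 2).
#' @return Data frame `sample chrom dp_start dp_end bp_start bp_end state
#'   n_ret_hom n_max_hom n_het n_missing n_windows`, `state` in
#'   `{RET/RET, MAX/MAX, RET/MAX, UNDET}`.
#' @export
call_windows <- function(calls, dps, win = 20L, min_scored = 10L, ratio = 2) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list("sample", NULL))
  if (ncol(calls) != nrow(dps))
    stop("call matrix does not match the panel size")
  blocks <- dp_window_blocks(dps, win)
  out <- lapply(rownames(calls), function(s) {
    row <- calls[s, ]
    res <- blocks
    counts <- t(vapply(seq_len(nrow(blocks)), function(k) {
      v <- row[blocks$dp_start[k]:blocks$dp_end[k]]
      c(n_ret_hom = sum(v == DP_RET_HOM), n_max_hom = sum(v == DP_MAX_HOM),
        n_het = sum(v == DP_HET), n_missing = sum(v == DP_MISSING))
    }, integer(4)))
    res <- cbind(res, as.data.frame(counts))
    res$state <- apply(counts, 1, function(cn) {
      scored <- cn[1] + cn[2] + cn[3]
      if (scored < min_scored) return("UNDET")
      srt <- sort(cn[1:3], decreasing = TRUE)
      best <- srt[1]; second <- srt[2]
      if (best == 0) return("UNDET")
      if (second > 0 && best / second < ratio) return("UNDET")
      if (second > 0 && best == second) return("UNDET")
      c("RET/RET", "MAX/MAX", "RET/MAX")[which.max(cn[1:3])]
    })
    res$sample <- s
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$n_windows <- 1L
  out[c("sample", "chrom", "dp_start", "dp_end", "bp_start", "bp_end",
        "state", "n_ret_hom", "n_max_hom", "n_het", "n_missing", "n_windows")]
}

#' Merge window-state runs into karyotype segments
#'
#' Maximal runs of identical window state on a chromosome merge into one
#' segment spanning from the position of the first DP of the first window to
#' the last DP of the last window; undetermined runs merge like any state.
#' Genotype-configuration counts are summed over the merged windows, so the
#' merge is lossless up to window boundaries.
#'
#' @param windows Window table from [call_windows()].
#' @return Data frame `sample chrom bp_start bp_end state n_windows
#'   n_ret_hom n_max_hom n_het n_missing`.
#' @export
merge_to_segments <- function(windows) {
  out <- lapply(split(windows, windows[c("sample", "chrom")], drop = TRUE),
                function(d) {
    d <- d[order(d$bp_start), , drop = FALSE]
    r <- rle(d$state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(
      sample = d$sample[1], chrom = d$chrom[1],
      bp_start = d$bp_start[starts], bp_end = d$bp_end[ends],
      state = r$values,
      n_windows = as.integer(r$lengths),
      n_ret_hom = vapply(seq_along(starts), function(k)
        sum(d$n_ret_hom[starts[k]:ends[k]]), integer(1)),
      n_max_hom = vapply(seq_along(starts), function(k)
        sum(d$n_max_hom[starts[k]:ends[k]]), integer(1)),
      n_het = vapply(seq_along(starts), function(k)
        sum(d$n_het[starts[k]:ends[k]]), integer(1)),
      n_missing = vapply(seq_along(starts), function(k)
        sum(d$n_missing[starts[k]:ends[k]]), integer(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$sample, suppressWarnings(as.numeric(out$chrom)),
                   out$chrom, out$bp_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide admixture proportions from DP calls
#'
#' `prop_max = (2 n_MAX_HOM + n_HET) / (2 n_scored)`: the fraction of scored
#' diagnostic alleles of MAX origin; `prop_ret = 1 - prop_max`. Missing DPs
#' are excluded; a sample with zero scored DPs is flagged undefined.
#'
#' @param calls A `dp_call_matrix` or one row of it.
#' @return Data frame `sample prop_ret prop_max n_dp_used`.
#' @export
admixture_proportion <- function(calls) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list("sample", NULL))
  out <- lapply(rownames(calls), function(s) {
    v <- calls[s, ]
    n_max <- sum(v == DP_MAX_HOM); n_het <- sum(v == DP_HET)
    n_scored <- sum(v != DP_MISSING)
    p <- if (n_scored == 0) NA_real_ else (2 * n_max + n_het) / (2 * n_scored)
    data.frame(sample = s, prop_ret = 1 - p, prop_max = p,
               n_dp_used = n_scored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write karyotype segments or admixture proportions
#'
#' Segments go to a BED-like TSV (1-based inclusive coordinates, unlike
#' standard BED); admixture to TSV `sample prop_ret prop_max n_dp_used`.
#'
#' @param segments Segment table from [merge_to_segments()].
#' @param admixture Table from [admixture_proportion()].
#' @param path Output file path.
#' @export
write_karyotype_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_karyotype_segments
#' @export
write_admixture <- function(admixture, path) {
  utils::write.table(admixture, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot phylogenomic karyotypes
#'
#' Horizontal chromosome bars per sample: red RET/RET, blue MAX/MAX, purple
#' RET/MAX, grey undetermined.
#'
#' @param segments Segment table from [merge_to_segments()].
#' @return A ggplot object.
#' @export
plot_karyotype <- function(segments) {
  cols <- c("RET/RET" = "#c0392b", "MAX/MAX" = "#2e6da4",
            "RET/MAX" = "#7d3c98", "UNDET" = "grey70")
  segments$chrom <- factor(segments$chrom,
                           levels = unique(segments$chrom[
                             order_loci(data.frame(chrom = segments$chrom,
                                                   pos = segments$bp_start))]))
  ggplot2::ggplot(segments,
                  ggplot2::aes(xmin = bp_start / 1e6, xmax = bp_end / 1e6,
                               ymin = 0, ymax = 1, fill = state)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(sample ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = cols, name = "ancestry") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
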