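# Sliding-window machinery shared by the heterozygosity scan, the
# centroid-similarity scan and the windowed-Ho distribution. Windows live in
# marker-index space; bp spans are derived from the first/last marker
# positions of each window.

# Window index spans over n markers: full windows of `win` markers starting
# every `step`; after the last full window, one final partial window is
# emitted if it holds >= win/2 markers, otherwise the last window is extended
# to the chromosome end. Fewer than win/2 markers overall -> a single
# whole-chromosome window (with a warning from callers that care).
window_spans <- function(n, win, step) {
  stopifnot(win >= 1, step >= 1, step <= win)
  if (n < win / 2)
    return(data.frame(start = 1L, end = as.integer(n)))
  starts <- seq.int(1L, n, by = step)
  full <- starts[starts + win - 1L <= n]
  if (!length(full))                       # win/2 <= n < win
    return(data.frame(start = 1L, end = as.integer(n)))
  spans <- data.frame(start = as.integer(full),
                      end = as.integer(full + win - 1L))
  nxt <- full[length(full)] + step
  if (nxt <= n) {
    tail_n <- n - nxt + 1L
    if (tail_n >= win / 2) {
      spans <- rbind(spans, data.frame(start = as.integer(nxt),
                                       end = as.integer(n)))
    } else {
      spans$end[nrow(spans)] <- as.integer(n)
    }
  }
  spans
}

#' Moving-average track of a per-marker statistic
#'
#' Averages `values` (one entry per marker of a single chromosome, `NA`
#' allowed and skipped) in windows of `win` markers advanced by `step`
#' markers. A final partial window is emitted when it contains at least
#' `win/2` markers and otherwise merged into the previous window; a
#' chromosome with fewer than `win/2` markers yields a single
#' whole-chromosome window with a warning.
#'
#' @param values Numeric per-marker statistic.
#' @param pos Marker bp positions (sorted ascending).
#' @param win Window size in markers.
#' @param step Step between window starts in markers (`<= win`).
#' @return Data frame `win_start_idx win_end_idx bp_start bp_end value
#'   n_markers` (indices 1-based inclusive; `value` the mean of non-missing
#'   entries).
#' @export
windowed_statistic <- function(values, pos, win, step) {
  n <- length(values)
  if (length(pos) != n) stop("`values` and `pos` lengths differ")
  if (is.unsorted(pos)) stop("`pos` must be sorted ascending")
  if (n < win / 2)
    warning("fewer than win/2 markers; single whole-chromosome window")
  spans <- window_spans(n, win, step)
  value <- mapply(function(s, e) {
    v <- values[s:e]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, spans$start, spans$end)
  data.frame(win_start_idx = spans$start, win_end_idx = spans$end,
             bp_start = pos[spans$start], bp_end = pos[spans$end],
             value = as.numeric(value),
             n_markers = spans$end - spans$start + 1L)
}

# apply windowed_statistic chromosome by chromosome
track_by_chrom <- function(loci, values, win, step) {
  out <- lapply(split(seq_len(nrow(loci)), loci$chrom), function(idx) {
    idx <- idx[order(loci$pos[idx])]
    tr <- windowed_statistic(values[idx], loci$pos[idx], win, step)
    tr$chrom <- loci$chrom[idx[1]]
    tr
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order_loci(data.frame(chrom = out$chrom, pos = out$bp_start)), ]
}

#' Windowed heterozygosity track of one sample
#'
#' Per-marker heterozygosity indicator (1 heterozygous, 0 homozygous,
#' missing skipped) averaged in moving windows per chromosome. Defaults are
#' the introgression-scan windows (120 markers, step 40); the
#' heterozygosity-distribution analysis uses non-overlapping 100-marker
#' windows (`win = 100, step = 100`).
#'
#' @param gm A [genotype_matrix()].
#' @param sample A sample id.
#' @param win,step Window size and step in markers.
#' @return Data frame with `chrom` plus the [windowed_statistic()] columns.
#' @export
heterozygosity_track <- function(gm, sample, win = 120L, step = 40L) {
  if (!sample %in% gm$samples) stop("unknown sample: ", sample)
  het <- as.numeric(gm$dosage[sample, ] == 1L)   # NA propagates
  tr <- track_by_chrom(gm$loci, het, win, step)
  tr$sample <- sample
  tr[c("sample", "chrom", "win_start_idx", "win_end_idx",
       "bp_start", "bp_end", "value", "n_markers")]
}

#' Windowed similarity of one sample to the two taxon centroids
#'
#' Restricted to loci informative for the two-taxon differentiation
#' (first-pass `G_ST > min_gst` on unmasked reference frequencies), the
#' per-locus centroid similarities are averaged in moving windows
#' (default 60 markers, step 20). Both tracks share the same window grid.
#'
#' @param gm A [genotype_matrix()].
#' @param sample A sample id.
#' @param cen_ret,cen_max Centroid profiles of the two reference sets
#'   ([taxon_centroid()]).
#' @param gst1 Per-locus first-pass G_ST (same locus order as `gm`).
#' @param win,step Window size and step in markers.
#' @param min_gst Informativeness threshold (default 0.5, exclusive).
#' @return Data frame `sample chrom win_start_idx win_end_idx bp_start
#'   bp_end s_ret s_max n_markers`.
#' @export
similarity_tracks <- function(gm, sample, cen_ret, cen_max, gst1,
                              win = 60L, step = 20L, min_gst = 0.5) {
  if (length(gst1) != nrow(gm$loci))
    stop("`gst1` length does not match the locus count")
  keep <- !is.na(gst1) & gst1 > min_gst &
    !is.na(cen_ret$p_alt) & !is.na(cen_max$p_alt)
  if (!any(keep)) stop("no informative loci at G_ST > ", min_gst)
  s_ret <- similarity_to_centroid(gm, sample, cen_ret)[keep]
  s_max <- similarity_to_centroid(gm, sample, cen_max)[keep]
  loci <- gm$loci[keep, , drop = FALSE]
  tr_r <- track_by_chrom(loci, s_ret, win, step)
  tr_m <- track_by_chrom(loci, s_max, win, step)
  out <- tr_r
  names(out)[names(out) == "value"] <- "s_ret"
  out$s_max <- tr_m$value
  out$sample <- sample
  out[c("sample", "chrom", "win_start_idx", "win_end_idx",
        "bp_start", "bp_end", "s_ret", "s_max", "n_markers")]
}

#' Windowed-heterozygosity distribution table
#'
#' Heterozygosity of each sample in successive non-overlapping windows of
#' `win` markers, with a binned frequency summary (bin width 0.05): the
#' genome-fragment heterozygosity distribution that separates intraspecific
#' from interspecific haplotype combinations.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Sample ids (default all).
#' @param win Window size in markers (default 100, non-overlapping).
#' @param bin Histogram bin width (default 0.05).
#' @return List with `windows` (per-sample window table) and `distribution`
#'   (per-sample bin frequencies: `sample bin_lo bin_hi n frequency`).
#' @export
heterozygosity_distribution <- function(gm, samples = gm$samples,
                                        win = 100L, bin = 0.05) {
  wins <- do.call(rbind, lapply(samples, function(s)
    heterozygosity_track(gm, s, win = win, step = win)))
  breaks <- seq(0, 1, by = bin)
  dist <- do.call(rbind, lapply(samples, function(s) {
    v <- wins$value[wins$sample == s & !is.na(wins$value)]
    cut_idx <- pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                    length(breaks) - 1L)
    n <- tabulate(cut_idx, nbins = length(breaks) - 1L)
    data.frame(sample = s, bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1], n = n,
               frequency = if (sum(n)) n / sum(n) else NA_real_)
  }))
  rownames(dist) <- NULL
  list(windows = wins, distribution = dist)
}
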