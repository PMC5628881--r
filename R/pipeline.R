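# End-to-end orchestration: discovery (filters -> first-pass G_ST ->
# introgression masking -> masked G_ST -> DP panel) and painting (DP calls
# -> window states -> segments -> admixture), with a single config object
# holding every threshold.

#' Pipeline configuration
#'
#' All tunable thresholds of the workflow with their default values:
#' `min_reads` 5 (call-level depth filter), `max_missing` 0.5 and `min_maf`
#' 0.05 (locus filter over all samples), `max_ref_missing` 0.3 (locus filter
#' over the references), `informative_gst` 0.5 (loci feeding the similarity
#' scan), `ho_threshold` 0.40 (introgression trigger), `ho_win`/`ho_step`
#' 120/40 and `sim_win`/`sim_step` 60/20 (scan windows), `dist_win` 100
#' (heterozygosity-distribution windows), `dp_gst` 0.9 (DP selection),
#' `karyo_win` 20, `min_scored` 10 and `ratio` 2 (window calling).
#'
#' @param ... Named overrides of the defaults above; also `seed` (integer or
#'   `NULL`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_reads = 5L, max_missing = 0.5, min_maf = 0.05, max_ref_missing = 0.3,
    informative_gst = 0.5, ho_threshold = 0.40,
    ho_win = 120L, ho_step = 40L, sim_win = 60L, sim_step = 20L,
    dist_win = 100L, dp_gst = 0.9,
    karyo_win = 20L, min_scored = 10L, ratio = 2, seed = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the discovery stage
#'
#' Applies the depth filter (when a depth matrix is given), the locus
#' missingness/MAF filter and the reference-missingness filter; computes
#' first-pass reference centroids and G_ST; scans every reference accession
#' for introgressions and masks them; re-estimates taxon frequencies and
#' G_ST on the masked data; and selects the diagnostic panel. The whole
#' stage is deterministic given its inputs.
#'
#' @param gm A [genotype_matrix()].
#' @param panel Sample panel data frame (`sample role`).
#' @param depth Optional [depth_matrix()].
#' @param config A [pipeline_config()].
#' @param mask If `FALSE`, skip introgression masking (for before/after
#'   comparison of the masking effect).
#' @return List: `gm_filtered`, `gm_masked`, `masks`, `gst1` (per-locus
#'   first-pass G_ST), `gst_table` (masked per-locus frequencies and G_ST),
#'   `dp_panel`, `stats` (per-locus Ho/He/Fw/GST table) and `config`.
#' @export
run_discovery <- function(gm, panel, depth = NULL,
                          config = pipeline_config(), mask = TRUE) {
  check_panel(panel, gm)
  if (!is.null(depth))
    gm <- apply_depth_threshold(gm, depth, config$min_reads)
  gm <- filter_loci(gm, config$max_missing, config$min_maf)
  gm <- filter_by_reference_missing(gm, panel, config$max_ref_missing)
  if (mask) {
    masks <- scan_reference_introgressions(
      gm, panel, ho_threshold = config$ho_threshold,
      informative_gst = config$informative_gst,
      ho_win = config$ho_win, ho_step = config$ho_step,
      sim_win = config$sim_win, sim_step = config$sim_step)
    gst1 <- attr(masks, "gst1")
    gm_masked <- apply_mask(gm, masks)
  } else {
    masks <- data.frame(sample = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
    f_ret <- allele_frequencies(gm, panel_samples(panel, "RET_REF"))
    f_max <- allele_frequencies(gm, panel_samples(panel, "MAX_REF"))
    gst1 <- nei_gst(f_ret$p_alt, f_max$p_alt)
    gm_masked <- gm
  }
  gst_table <- compute_gst_ret_max(gm_masked, panel)
  dp_panel <- select_diagnostic_panel(gst_table, gm_masked, config$dp_gst)
  stats <- locus_stats_table(gm, panel,
                             mask = if (nrow(masks)) masks else NULL)
  list(gm_filtered = gm, gm_masked = gm_masked, masks = masks,
       gst1 = gst1, gst_table = gst_table, dp_panel = dp_panel,
       stats = stats, config = config)
}

#' Run the painting stage
#'
#' Classifies every requested sample's calls against the diagnostic panel,
#' calls karyotype windows, merges them into segments and estimates
#' genome-wide admixture proportions; also emits the windowed-heterozygosity
#' distribution (non-overlapping `dist_win`-marker windows). Reference
#' accessions are painted alongside queries by default.
#'
#' @param gm The filtered [genotype_matrix()] (unmasked: painting uses every
#'   call).
#' @param dp_panel A `diagnostic_panel`.
#' @param samples Samples to paint (default: all samples of `gm`). Samples
#'   absent from `gm` are skipped with a warning.
#' @param config A [pipeline_config()].
#' @return List: `calls` (`dp_call_matrix`), `windows`, `segments`,
#'   `admixture`, `ho_distribution` (list of window table and binned
#'   frequencies) and `config`.
#' @export
run_painting <- function(gm, dp_panel, samples = gm$samples,
                         config = pipeline_config()) {
  if (!nrow(dp_panel)) stop("empty diagnostic panel")
  absent <- setdiff(samples, gm$samples)
  if (length(absent)) {
    warning("sample(s) absent from genotype matrix, skipped: ",
            paste(absent, collapse = ", "))
    samples <- setdiff(samples, absent)
  }
  if (!length(samples)) stop("no sample to paint")
  sub <- subset_samples(gm, samples)
  calls <- classify_dp_genotypes(sub, dp_panel)
  windows <- call_windows(calls, dp_panel, win = config$karyo_win,
                          min_scored = config$min_scored,
                          ratio = config$ratio)
  segments <- merge_to_segments(windows)
  admixture <- admixture_proportion(calls)
  ho_dist <- heterozygosity_distribution(sub, win = config$dist_win)
  list(calls = calls, windows = windows, segments = segments,
       admixture = admixture, ho_distribution = ho_dist, config = config)
}
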