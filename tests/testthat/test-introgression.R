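# Introgression detection in reference accessions and interval masking.

test_that("no flag when Ho is low and own-taxon similarity dominates", {
  ho <- data.frame(chrom = "1", bp_start = c(1L, 4e6), bp_end = c(4e6, 8e6),
                   value = c(0.12, 0.28))
  sim <- data.frame(chrom = "1", bp_start = c(1L, 4e6), bp_end = c(4e6, 8e6),
                    s_ret = c(0.9, 0.85), s_max = c(0.3, 0.4))
  out <- detect_introgressions(ho, sim, "RET")
  expect_equal(nrow(out), 0L)
  # the (0.30, 0.40] gap is not flagged by the Ho condition alone
  ho$value <- c(0.35, 0.40)
  expect_equal(nrow(detect_introgressions(ho, sim, "RET")), 0L)
  # ... but the same windows flag through the similarity condition
  sim$s_max <- c(0.95, 0.4)
  out2 <- detect_introgressions(ho, sim, "RET")
  expect_equal(out2, data.frame(chrom = "1", start = 1L, end = 4e6))
})

test_that("overlapping and adjacent flagged windows union into intervals", {
  ho <- data.frame(chrom = rep("1", 5),
                   bp_start = c(1, 100, 200, 500, 700) * 1e3,
                   bp_end = c(150, 250, 350, 650, 850) * 1e3,
                   value = c(0.5, 0.1, 0.45, 0.6, 0.1))
  sim <- data.frame(chrom = "1", bp_start = 1L, bp_end = 850e3,
                    s_ret = 0.9, s_max = 0.1)
  out <- detect_introgressions(ho, sim, "RET")
  # windows 1 and 3 overlap window 2's span? no: 1 ends 150k, 3 starts 200k
  expect_equal(out$start, c(1, 200, 500) * 1e3)
  expect_equal(out$end, c(150, 350, 650) * 1e3)
})

test_that("apply_mask equals a brute-force per-cell containment check", {
  set.seed(401)
  d <- matrix(sample(c(0:2, NA), 4 * 50, replace = TRUE), nrow = 4)
  rownames(d) <- c("a", "b", "c", "q")
  gm <- toy_gm(d, chrom = rep(c("1", "2"), each = 25),
               pos = rep(seq_len(25) * 100L, 2))
  masks <- data.frame(sample = c("a", "a", "c"),
                      chrom = c("1", "2", "1"),
                      start = c(300L, 1000L, 2400L),
                      end = c(900L, 1800L, 2500L))
  out <- apply_mask(gm, masks)
  for (s in rownames(d)) for (k in seq_len(ncol(d))) {
    inside <- any(masks$sample == s & masks$chrom == gm$loci$chrom[k] &
                    gm$loci$pos[k] >= masks$start & gm$loci$pos[k] <= masks$end)
    if (inside) expect_true(is.na(out$dosage[s, k]))
    else expect_identical(out$dosage[s, k], gm$dosage[s, k])
  }
  # empty mask is identity; unknown chromosome errors
  expect_identical(apply_mask(gm, masks[0, ]), gm)
  expect_identical(apply_mask(gm, NULL), gm)
  expect_error(apply_mask(gm, data.frame(sample = "a", chrom = "7",
                                         start = 1L, end = 2L)),
               "unknown chromosome")
  # masking is monotone: adding an interval never restores a call
  more <- rbind(masks, data.frame(sample = "b", chrom = "2",
                                  start = 1L, end = 2500L))
  out2 <- apply_mask(gm, more)
  expect_true(all(is.na(out2$dosage[is.na(out$dosage)])))
  # whole-chromosome mask empties exactly that sample's chromosome
  expect_true(all(is.na(out2$dosage["b", gm$loci$chrom == "2"])))
  expect_identical(out2$dosage["q", ], gm$dosage["q", ])
})

test_that("mask set round-trips through its TSV export", {
  masks <- data.frame(sample = c("a", "b"), chrom = c("1", "2"),
                      start = c(10L, 20L), end = c(100L, 200L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mask_set(masks, path)
  expect_equal(read_mask_set(path), masks)
})

test_that("clean references yield a near-empty mask (false-positive control)", {
  cohort <- toy_cohort(402, n_chrom = 3, loci_per_chrom = 700)
  masks <- scan_reference_introgressions(cohort$gm, cohort$panel)
  genome_bp <- sum(cohort$model$chrom_lengths)
  masked_bp <- if (nrow(masks)) sum(tapply(masks$end - masks$start + 1,
                                           masks$sample, sum)) /
                  nrow(cohort$panel) else 0
  expect_lt(masked_bp / genome_bp, 0.05)
})

test_that("a planted heterozygous block is recovered with high overlap", {
  model <- simulate_ancestral_model(n_chrom = 2, loci_per_chrom = 2000,
                                    seed = 403)
  intro <- introgression_spec(model, "RET", "1", from = 1e7, to = 1.8e7)
  refs <- simulate_reference_panel(model,
                                   introgressions = list(RET_03 = intro),
                                   seed = 404)
  gm <- refs$genotypes
  # elevated Ho only inside the planted block
  tr <- heterozygosity_track(gm, "RET_03")
  inside <- tr$chrom == "1" & tr$bp_start >= 1e7 & tr$bp_end <= 1.8e7
  outside <- !(tr$chrom == "1" & tr$bp_end >= 1e7 & tr$bp_start <= 1.8e7)
  expect_true(all(tr$value[inside] > 0.4))
  expect_true(all(tr$value[outside] < 0.4))
  masks <- scan_reference_introgressions(gm, refs$panel)
  got <- masks[masks$sample == "RET_03" & masks$chrom == "1", ]
  expect_equal(nrow(got), 1L)
  inter <- max(0, min(got$end, 1.8e7) - max(got$start, 1e7) + 1)
  union <- max(got$end, 1.8e7) - min(got$start, 1e7) + 1
  expect_gt(inter / (1.8e7 - 1e7 + 1), 0.90)   # covers >= 90% of truth
  expect_gt(inter / union, 0.8)                # Jaccard
})

test_that("het-hom-het introgression merges into one interval (worked logic)", {
  model <- simulate_ancestral_model(n_chrom = 2, loci_per_chrom = 2000,
                                    seed = 405)
  len <- model$chrom_lengths[["2"]]
  # chromosome 2 from 20 Mb to the end: het MAX, then a hom MAX stretch
  # (24-29 Mb, where homolog 2 is MAX too), then het MAX again
  blocks <- rbind(
    data.frame(chrom = "1", homolog = 1:2, start = 1,
               end = model$chrom_lengths[["1"]], taxon = "RET"),
    data.frame(chrom = "2", homolog = 1L, start = c(1, 2.0e7),
               end = c(2.0e7 - 1, len), taxon = c("RET", "MAX")),
    data.frame(chrom = "2", homolog = 2L, start = c(1, 2.4e7, 2.9e7),
               end = c(2.4e7 - 1, 2.9e7 - 1, len),
               taxon = c("RET", "MAX", "RET"))
  )
  intro <- spec_blocks(model, blocks)
  refs <- simulate_reference_panel(model,
                                   introgressions = list(RET_01 = intro),
                                   seed = 406)
  masks <- scan_reference_introgressions(refs$genotypes, refs$panel)
  got <- masks[masks$sample == "RET_01" & masks$chrom == "2", ]
  expect_equal(nrow(got), 1L)            # single merged interval
  expect_lt(got$start, 2.05e7)           # starts near the first het block
  expect_gt(got$end, 0.98 * len)         # runs to the chromosome end
})

test_that("a homozygous block is caught by the similarity condition", {
  model <- simulate_ancestral_model(n_chrom = 2, loci_per_chrom = 2000,
                                    seed = 407)
  intro <- introgression_spec(model, "MAX", "2", from = 5e6, to = 1.5e7,
                              homozygous = TRUE)
  refs <- simulate_reference_panel(model,
                                   introgressions = list(MAX_04 = intro),
                                   seed = 408)
  gm <- refs$genotypes
  cen_ret <- taxon_centroid(gm, refs$panel$sample[refs$panel$role == "RET_REF"])
  cen_max <- taxon_centroid(gm, refs$panel$sample[refs$panel$role == "MAX_REF"])
  gst1 <- nei_gst(cen_ret$p_alt, cen_max$p_alt)
  tr <- similarity_tracks(gm, "MAX_04", cen_ret, cen_max, gst1)
  crossed <- tr$chrom == "2" & tr$s_ret >= tr$s_max
  expect_true(any(crossed))
  expect_true(all(tr$bp_end[crossed] >= 5e6 & tr$bp_start[crossed] <= 1.5e7))
  masks <- scan_reference_introgressions(gm, refs$panel)
  got <- masks[masks$sample == "MAX_04" & masks$chrom == "2", ]
  expect_gte(nrow(got), 1L)
  expect_lt(abs(min(got$start) - 5e6), 2e6)
  expect_lt(abs(max(got$end) - 1.5e7), 2e6)
})
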