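# Allele frequencies, diversity statistics, G_ST, dissimilarities and
# centroid similarity against hand oracles and closed-form properties.

test_that("allele frequencies: fixed, mixed, and mask-aware counting", {
  gm <- toy_gm(rbind(c(2L, 1L, NA), c(2L, 0L, 1L)))
  f <- allele_frequencies(gm)
  expect_equal(f$p_alt, c(1, 0.25, 0.5))
  expect_equal(f$n_obs, c(2L, 2L, 1L))
  # all-missing locus flagged undefined, not raised
  f1 <- allele_frequencies(subset_samples(gm, "S01"))
  expect_true(is.na(f1$p_alt[3]) && f1$n_obs[3] == 0)
})

test_that("masked cells are excluded exactly as a brute-force count", {
  set.seed(201)
  d <- matrix(sample(c(0:2, NA), 11 * 30, replace = TRUE), nrow = 11)
  rownames(d) <- sprintf("R%02d", 1:11)
  gm <- toy_gm(d)
  mask <- data.frame(sample = c("R01", "R05"), chrom = "1",
                     start = c(100L, 900L), end = c(500L, 1600L))
  f <- allele_frequencies(gm, mask = mask)
  for (k in c(1, 5, 9, 16, 30)) {
    alt <- 0L; nobs <- 0L
    for (s in rownames(d)) {
      masked <- any(mask$sample == s & gm$loci$pos[k] >= mask$start &
                      gm$loci$pos[k] <= mask$end)
      if (!masked && !is.na(d[s, k])) {
        alt <- alt + unname(d[s, k]); nobs <- nobs + 1L
      }
    }
    expect_equal(f$n_obs[k], nobs)
    if (nobs > 0) expect_equal(f$p_alt[k], alt / (2 * nobs))
  }
})

test_that("locus diversity matches the direct formulas", {
  # p = 0.5 -> He = 0.5; all-het -> Ho = 1, Fw = -1
  gm <- toy_gm(rbind(c(1L, 1L, 0L, 2L), c(1L, 1L, 0L, 0L)))
  dv <- locus_diversity(gm)
  expect_equal(dv$He[1], 0.5)
  expect_equal(dv$Ho[1], 1)
  expect_equal(dv$Fw[1], -1)
  expect_true(is.na(dv$Fw[3]))          # monomorphic: Fw undefined
  expect_equal(dv$He[3], 0)
  # random 20-sample locus against a hand oracle
  set.seed(202)
  d <- matrix(sample(c(0:2, NA), 20, replace = TRUE), ncol = 1)
  rownames(d) <- sprintf("S%02d", 1:20)
  dv2 <- locus_diversity(toy_gm(d))
  col <- d[!is.na(d), 1]
  p <- sum(col) / (2 * length(col))
  expect_equal(dv2$Ho, mean(col == 1))
  expect_equal(dv2$He, 1 - p^2 - (1 - p)^2)
  expect_equal(dv2$Fw, 1 - mean(col == 1) / (1 - p^2 - (1 - p)^2))
})

test_that("Fw is near zero under Hardy-Weinberg simulation", {
  set.seed(203)
  p <- runif(50, 0.2, 0.8)
  d <- vapply(p, function(pp) rbinom(500, 2, pp), integer(500))
  rownames(d) <- sprintf("S%03d", 1:500)
  dv <- locus_diversity(toy_gm(d, pos = seq_len(50) * 10L))
  # pooled fixation index over loci
  expect_lt(abs(1 - mean(dv$Ho) / mean(dv$He)), 0.05)
  expect_lt(abs(mean(dv$Fw)), 0.05)
})

test_that("sample heterozygosity excludes missing calls", {
  gm <- toy_gm(rbind(c(1L, 0L, 2L, NA), c(1L, 1L, 1L, 1L)))
  expect_equal(sample_heterozygosity(gm, "S01"), 1 / 3)
  expect_equal(sample_heterozygosity(gm, "S02"), 1)
  expect_equal(sample_heterozygosity(gm, "S01", loci = 1:2), 1 / 2)
  expect_true(is.na(sample_heterozygosity(gm, "S01", loci = 4)))
})

test_that("Nei G_ST: closed-form values and grid properties", {
  expect_equal(nei_gst(1, 0), 1)
  expect_equal(nei_gst(0.3, 0.3), 0)
  # hand evaluation: He_a = He_b = 0.18, He_tot = 0.5
  expect_equal(nei_gst(0.9, 0.1), 0.64)
  expect_true(is.na(nei_gst(0, 0)))       # monomorphic pooled locus
  expect_true(is.na(nei_gst(NA, 0.5)))
  grid <- expand.grid(pa = seq(0, 1, 0.05), pb = seq(0, 1, 0.05))
  g <- nei_gst(grid$pa, grid$pb)
  defined <- !is.na(g)
  expect_true(all(g[defined] >= 0 & g[defined] <= 1))
  expect_equal(g, nei_gst(grid$pb, grid$pa))            # symmetry
  same <- grid$pa == grid$pb & grid$pa > 0 & grid$pa < 1
  expect_true(all(g[same] == 0))
})

test_that("dissimilarities match allele-matching and dosage oracles", {
  gm <- toy_gm(rbind(c(0L, 1L, 2L, 0L, 1L),
                     c(0L, 1L, 2L, 0L, 1L),
                     c(2L, 2L, 2L, 2L, 2L),
                     c(1L, NA, 0L, 2L, 1L)))
  expect_equal(simple_matching_dissimilarity(gm, "S01", "S02"), 0)
  expect_equal(euclidean_dissimilarity(gm, "S01", "S02"), 0)
  # ref/ref vs alt/alt at every locus -> d = 1
  gm2 <- toy_gm(rbind(a = c(0L, 0L), b = c(2L, 2L)))
  expect_equal(simple_matching_dissimilarity(gm2, "a", "b"), 1)
  # single locus ref/ref vs ref/alt -> one shared allele -> 0.5; dosage 0 vs 2 -> 2
  gm3 <- toy_gm(rbind(a = 0L, b = 1L, c = 2L))
  expect_equal(simple_matching_dissimilarity(gm3, "a", "b"), 0.5)
  expect_equal(euclidean_dissimilarity(gm3, "a", "c"), 2)
  # 5-locus pair against explicit hand oracles (pairwise-complete only)
  x <- c(1L, NA, 0L, 2L, 1L); y <- c(0L, 1L, 2L, 0L, 1L)
  m <- c(1, 0, 0, 2) / 2                    # loci 1,3,4,5
  expect_equal(simple_matching_dissimilarity(gm, "S04", "S01"), 1 - mean(m))
  expect_equal(euclidean_dissimilarity(gm, "S04", "S01"),
               sqrt(sum((x[-2] - y[-2])^2)))
  # no pairwise-complete loci -> undefined
  gm4 <- toy_gm(rbind(a = c(1L, NA), b = c(NA, 1L)))
  expect_true(is.na(simple_matching_dissimilarity(gm4, "a", "b")))
})

test_that("dissimilarity matrix is symmetric with correct pair counts", {
  set.seed(204)
  d <- matrix(sample(c(0:2, NA), 5 * 40, replace = TRUE), nrow = 5)
  rownames(d) <- sprintf("S%02d", 1:5)
  gm <- toy_gm(d)
  for (metric in c("euclidean", "simple_matching")) {
    dm <- dissimilarity_matrix(gm, metric)
    expect_equal(dm$d, t(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 5))
    expect_equal(dm$d["S01", "S03"],
                 if (metric == "euclidean")
                   euclidean_dissimilarity(gm, "S01", "S03")
                 else simple_matching_dissimilarity(gm, "S01", "S03"))
    expect_equal(dm$L["S02", "S04"],
                 sum(!is.na(d[2, ]) & !is.na(d[4, ])))
    if (metric == "simple_matching")
      expect_true(all(dm$d >= 0 & dm$d <= 1))
  }
})

test_that("centroid similarity: fixed points and S = 1 - d reduction", {
  gm <- toy_gm(rbind(c(2L, 2L, 1L, 0L, NA)))
  cen <- data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
                    p_alt = c(1, 0, 0.5, 0.25, 1), n_obs = 2L)
  s <- similarity_to_centroid(gm, "S01", cen)
  expect_equal(s[1], 1)      # alt/alt vs centroid p_alt = 1
  expect_equal(s[2], 0)      # alt/alt vs centroid p_alt = 0
  expect_equal(s[3], 0.5)    # het vs any centroid
  expect_equal(s[4], 0.75)
  expect_true(is.na(s[5]))   # missing call skipped
  # against a degenerate single-sample centroid, S = 1 - simple-matching d
  set.seed(205)
  d <- matrix(sample(0:2, 2 * 25, replace = TRUE), nrow = 2,
              dimnames = list(c("ind", "refsam"), NULL))
  gm2 <- toy_gm(d)
  cen2 <- taxon_centroid(gm2, "refsam")
  s2 <- similarity_to_centroid(gm2, "ind", cen2)
  d_per_locus <- 1 - (2 - abs(d["ind", ] - d["refsam", ])) / 2
  hom <- d["refsam", ] != 1   # a heterozygous "centroid" is a 50/50 pool
  expect_equal(s2[hom], (1 - d_per_locus)[hom])
  # identical to every member of a monomorphic reference set -> S = 1
  gm3 <- toy_gm(matrix(c(2L, 2L, 2L, 0L, 0L, 0L), nrow = 3,
                       dimnames = list(c("r1", "r2", "q"), NULL)))
  cen3 <- taxon_centroid(gm3, c("r1", "r2"))
  expect_equal(similarity_to_centroid(gm3, "q", cen3), c(1, 1))
})

test_that("taxon centroid equals allele frequencies on the same inputs", {
  set.seed(206)
  d <- matrix(sample(c(0:2, NA), 6 * 20, replace = TRUE), nrow = 6)
  rownames(d) <- sprintf("M%02d", 1:6)
  gm <- toy_gm(d)
  mask <- data.frame(sample = "M02", chrom = "1", start = 300L, end = 1200L)
  expect_equal(taxon_centroid(gm, rownames(d), mask),
               allele_frequencies(gm, rownames(d), mask))
  # single-sample centroid equals dosage / 2
  cen1 <- taxon_centroid(gm, "M01")
  ok <- !is.na(d[1, ])
  expect_equal(cen1$p_alt[ok], d[1, ok] / 2)
  # two fixed samples -> p_alt = 0.5
  gm2 <- toy_gm(matrix(c(0L, 2L), nrow = 2, dimnames = list(c("a", "b"), NULL)))
  expect_equal(taxon_centroid(gm2, c("a", "b"))$p_alt, 0.5)
})
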