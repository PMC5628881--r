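---
title: "Phylogenomic karyotyping from diagnostic polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenomic karyotyping from diagnostic polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many cultivated varieties are interspecific mosaics: their two haplotypes
descend, chromosome fragment by chromosome fragment, from two ancestral gene
pools (here called **RET** and **MAX**, after the mandarin/pummelo system
that motivates the defaults). Given a sparse biallelic genotype matrix —
reference accessions of both taxa plus admixed query varieties —
`phylokaryo` reconstructs each query's **phylogenomic karyotype**: the
per-chromosome sequence of local ancestry states `RET/RET`, `MAX/MAX`,
`RET/MAX` or undetermined, plus a genome-wide admixture proportion.

The workflow has two stages, exposed as `run_discovery()` and
`run_painting()` and driven end to end by the numbered scripts under
`analysis/`.

## Discovery

1. **Call and locus filters.** Calls with fewer than `min_reads = 5`
   supporting reads become missing. Loci are dropped when missing in more
   than `max_missing = 0.5` of all samples, when the minor allele frequency
   falls below `min_maf = 0.05`, or when missing in `max_ref_missing = 0.3`
   or more of the reference accessions (strict bound). Reduced-representation
   genotyping leaves substantial sparsity (the defaults assume roughly 12–13%
   missing calls), and these filters remove the loci where frequencies would
   be dominated by sampling noise.

2. **Reference introgression scan.** Reference accessions are themselves
   imperfect representatives: some carry introgressed fragments of the other
   taxon. Each reference is scanned with two complementary tracks:
   - windowed observed heterozygosity (`Ho`, 120 markers advanced by 40);
     a window is flagged when `Ho > 0.40`, far above the intra-taxon
     expectation — heterozygous introgressions combine one haplotype from
     each pool;
   - windowed similarity to the two taxon centroids (60 markers advanced by
     20, restricted to loci with first-pass `G_ST > 0.5`); a window is
     flagged when the *other* taxon's centroid similarity reaches or exceeds
     the own-taxon similarity — this catches *homozygous* introgressions,
     which show no excess heterozygosity. Centroid similarity is the
     expected allele-matching rate
     `S = (x·p + (2 − x)(1 − p)) / 2` of dosage `x` against centroid
     alt-frequency `p`.
   Flagged windows are unioned into bp intervals per chromosome and the
   affected calls are masked (set missing) before any frequency
   re-estimation.

3. **Diagnostic-polymorphism selection.** On the masked matrix, per-locus
   taxon frequencies give Nei's differentiation
   `G_ST = (He_tot − (He_ret + He_max)/2) / He_tot` with equal-weight
   pooling `p_tot = (p_ret + p_max)/2`, so the estimate does not depend on
   the panel-size imbalance. Loci with `G_ST ≥ 0.9` enter the diagnostic
   panel (`dp_gst = 0.9`); for multi-position indel records only the anchor
   position is eligible, preventing one event from contributing several
   pseudo-independent DPs. Each DP is oriented by the major allele of each
   taxon.

## Painting

Every sample × DP call becomes `RET_HOM`, `MAX_HOM`, `HET` or missing. Per
chromosome, successive non-overlapping windows of `karyo_win = 20` DPs are
called by a best/second rule: among the three configuration counts the
window takes the most frequent state when it has at least `min_scored = 10`
scored DPs and the best count is at least `ratio = 2` times the second
(a zero second count, i.e. a unanimous window, is called; an exact tie is
undetermined). Runs of identical window states merge into karyotype
segments, and the admixture proportion is
`prop_max = (2·n_MAX_HOM + n_HET) / (2·n_scored)`.

```{r workflow}
library(phylokaryo)

gm <- read_genotype_table("genotypes.tsv")
panel <- read_sample_panel("sample_panel.tsv")

disc <- run_discovery(gm, panel)
paint <- run_painting(disc$gm_filtered, disc$dp_panel)

paint$admixture
plot_karyotype(paint$segments)
```

## The synthetic-data generator

`simulate_ancestral_model()` draws two ancestral allele-frequency profiles:
a fraction `prop_fixed = 0.2` of loci are fixed differences (the truly
diagnostic fraction) and the rest draw independent per-taxon frequencies
from `Beta(0.3, 0.3)`. This calibration puts the mean true inter-taxon
`G_ST` at ≈ 0.47, the differentiation level the workflow is designed for;
`shared_mode = "identical"` instead gives undifferentiated taxa for negative
controls. Defaults: 9 chromosomes × 4,333 loci ≈ 39,000 loci on 33 Mb
chromosomes, a 22% indel fraction, an 11 + 6 reference panel and 12.6%
injected missingness — problem sizes chosen so a desk-scale run reproduces
the *regime* of a real GBS panel, not any particular dataset.

Genomes are simulated as ancestry-block mosaics (`spec_pure()`,
`spec_f1()`, `spec_bc()` with one crossover per chromosome per meiosis, or
explicit `spec_blocks()`), and genotypes are drawn per homolog from the
block's taxon frequency. `truth_windows()` converts a spec into the exact
expected state of every karyotype window, labelling windows that straddle an
ancestry breakpoint `BOUNDARY`.

What the generator does **not** emulate: linkage disequilibrium within a
gene pool, crossover interference or recombination hotspots, genotyping
error (beyond missingness), locus-dependent coverage, and any third ancestral
taxon.

## Numerical choices

- **Window grids.** Windows live in marker-index space; bp spans come from
  the first/last marker of each window. After the last full window, a
  partial tail window stands alone when it holds at least `win/2` markers
  and otherwise merges into the previous window; a chromosome with fewer
  than `win/2` markers becomes a single whole-chromosome window (with a
  warning). With overlapping grids (step < win) the tail rule applies to the
  last *start*, so an exactly-fitting chromosome still gets its trailing
  windows.
- **Detection rule.** A reference window is flagged by `Ho > 0.40`
  (strict) *or* `S_other ≥ S_own` (ties flag, conservatively, since a clean
  genome should be strictly closer to its own centroid). Flagged windows
  union over both tracks; touching or overlapping intervals merge.
- **Tie-breaks in window calling.** `best/second < 2` and exact ties are
  undetermined; unanimous windows (second count 0) are always called.
- **DP recall denominator.** Recovery of fixed-difference loci is measured
  among fixed loci that *survive the QC filters*: at 12.6% missingness the
  reference-missingness filter alone removes ≈ 1.4% of loci before
  selection ever sees them, and that attrition is a property of the data,
  not a selection miss.
- **Exactness regime.** Degenerate outcomes (pure queries at proportion
  exactly 0 or 1, an F1 at exactly 0.5) hold when every DP is a true fixed
  difference (`prop_fixed = 1`). Under the default regime a finite
  reference panel occasionally promotes a non-fixed locus past the observed
  `G_ST` threshold, so pure queries land near — not at — 0/1; accuracy there
  is assessed with tolerances (window accuracy ≥ 0.95, admixture error
  ≤ 0.02).

## Limitations

Two-taxon ancestry only; no uncertainty quantification on segment
boundaries (resolution is one 20-DP window); the reference scan assumes
introgressions are a minority of each reference genome (a reference that is
mostly admixed would bias the centroids it is compared against); and the
similarity scan needs enough informative (`G_ST > 0.5`) loci per chromosome
to form 60-marker windows.
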