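Package: phylokaryo
Title: Phylogenomic Karyotyping of Interspecific Admixture from
    Diagnostic Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the ancestral-species mosaic structure
    ("phylogenomic karyotype") of admixed genomes from a biallelic
    genotype matrix of two reference taxa plus query varieties.
    Implements the full workflow: depth/missingness/MAF filtering,
    sliding-window heterozygosity and centroid-similarity scans to
    detect and mask interspecific introgressions in the reference
    accessions, Nei G_ST-based selection of diagnostic polymorphisms of
    the two-taxon differentiation, window-based local-ancestry painting
    with genome-wide admixture proportions, and a synthetic-data
    generator producing ancestral gene pools, reference panels with
    planted introgressions, and admixed mosaic genomes with full ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
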