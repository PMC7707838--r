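Package: xqtl
Title: Bulk-Segregant Mapping of mRNA and Protein Expression QTLs from
    Sorted-Pool Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for X-QTL style bulk-segregant analysis of gene
    expression: allele-frequency tracks and delta-AF contrasts from
    pooled sequencing of fluorescence-sorted segregant pools, a binned
    hidden-frequency (MULTIPOOL-style) LOD scan, peak calling with
    2-LOD support intervals, replicate merging with an inter-replicate
    empirical false discovery rate, and classification of loci into
    concordant, discordant, mRNA-specific and protein-specific effects
    on mRNA production versus protein abundance.  Includes a synthetic
    yeast-cross simulator (recombinant haploid segregants, correlated
    dual-reporter single-cell phenotypes, FACS tail selection, pooled
    sequencing) so every pipeline stage can be tested against planted
    ground truth, plus flow-cytometry preprocessing (loess cell-size
    correction, channel correlation, sorted-pool heritability test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
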