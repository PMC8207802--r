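Package: domcost
Title: Genetic Load and Demographic Inference for Domestication Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genomic cost of domestication in a
    wild/domestic population pair: a discrete-generation Wright-Fisher
    forward simulator with a gamma distribution of fitness effects and a
    domestication-bottleneck demography; codon-aware coding-effect
    annotation with an alignment-based deleteriousness (delta) score;
    per-individual genetic-load accounting with heterozygous/homozygous
    partitions; sliding-window diversity and differentiation scans
    (pi, Hudson FST, locus-specific branch length, pi-ratio); and
    two-population joint site-frequency-spectrum demographic model
    fitting by numerical diffusion with AIC model selection and block
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
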