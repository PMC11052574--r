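Package: geitad
Title: Genetic-Epigenetic Interaction Modeling in Topologically Associating Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale analysis of non-additive interactions between
    genetic variants and chromatin accessibility in their effect on gene
    expression. Fits genotype-by-ATAC interaction regressions for
    gene-variant-peak trios with backward AIC term selection and F-tests,
    localizes significant interactions relative to topologically
    associating domains (TADs), classifies coefficient sign patterns
    (synergy, redundancy/interference), scans sequences for transcription
    factor binding motifs with exact score p-values, and validates
    genotype-predicted CTCF binding against replicate ChIP intensities.
    Includes a synthetic-data generator with planted ground truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
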