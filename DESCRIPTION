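Package: panpav
Title: Pan-Genome Presence/Absence Variation, Selection Scans and Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for crop pan-genome studies built around gene-family
    presence/absence matrices and structural-variant derived presence/absence
    variants (PAVs). Classifies gene families into core, soft-core, dispensable
    and private categories and fits permutation growth curves with a pan-genome
    closure verdict; scans PAV carrier frequencies across wild, landrace and
    cultivar groups for domestication- and improvement-selected variants with
    Fisher exact tests and FDR control; maps favorable PAVs to genes and
    promoters; detects target-site duplications to call high-confidence
    transposon-derived PAVs and tests TE overlap enrichment; computes sliding
    window nucleotide diversity, pi-ratio and Weir-Cockerham FST selection
    scans; runs EMMAX-style mixed-model association with effective-marker-number
    thresholds, greedy locus clustering, candidate-gene windows and SV-SNP
    linkage-disequilibrium complementarity; and performs genomic selection with
    gradient-boosted feature-gain marker panels, repeated-split prediction
    precision, and breeding-potential haplotype enumeration. A synthetic
    population generator with full ground truth exercises the whole pipeline
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
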