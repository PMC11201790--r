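Package: SSRtools
Title: Genome-Wide Microsatellite Marker Discovery, Diversity and
    Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for simple sequence repeat (SSR)
    marker studies in plant germplasm. Mines perfect microsatellites
    from genome assemblies under per-period minimum-repeat thresholds
    with strand- and phase-folded motif classes, designs flanking PCR
    primer pairs under product-size, length, Tm and GC constraints,
    assesses cross-species primer transferability by electronic PCR
    with 3'-anchor mismatch rules, computes per-locus genetic diversity
    statistics (Na, Ne, Ho, He, Shannon's I, Nei's H, PIC) from
    co-dominant diploid genotype tables, clusters germplasm by UPGMA
    and principal coordinates analysis, infers admixture structure by
    STRUCTURE-style Gibbs sampling with Evanno delta-K model choice,
    and runs GLM/MLM marker-trait association with a kinship random
    effect. A synthetic-data module generates genomes with planted SSR
    truth, structured diploid genotypes and phenotypes with known
    marker effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    rtracklayer,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
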