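Package: locuswave
Title: Wave-Based Evaluation of GWAS Locus-Nomination Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for benchmarking methods that nominate trait-associated
    loci from genome-wide association study (GWAS) summary statistics, using a
    later and larger GWAS wave of the same trait as the gold standard. Defines
    significant loci from summary statistics by stepwise +/-500 kb windowing
    with merging and extended-HLA collapsing, excludes loci already significant
    in the earlier wave, classifies nominations at the variant, locus, or gene
    level, computes sensitivity, positive predictive value and F1, ranks
    methods by competition (Olympic) ranking with median-rank aggregation, and
    builds UpSet-style ensemble membership matrices. Includes three built-in
    nomination procedures (suggestive p-value band, annotation-category
    thresholds, weighted-Bonferroni eQTL prioritisation), generic Bonferroni
    and Benjamini-Hochberg significance machinery, and a synthetic two-wave
    GWAS simulator with planted causal loci so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
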