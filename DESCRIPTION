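Package: snvconcord
Title: Concordance of Somatic SNV Calls Between Technical Sequencing
    Replicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures how reproducible somatic single-nucleotide variant
    (SNV) calls are between paired technical sequencing replicates of the
    same tumor.  Provides eight post-calling SNV filters (quality-score
    thresholds, loss-of-heterozygosity status, proximity to other SNVs or
    indels, dbSNP membership, and alternate-allele fraction), set-algebra
    statistics between paired call sets (overlap, per-replicate percent
    overlap, Jaccard similarity, difference-versus-overlap removal ratios),
    per-filter effect and complementarity measures, cohort summaries and
    rank correlations, and a seeded synthetic generator of paired
    replicate call sets with per-call ground truth for benchmarking the
    whole pipeline without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
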