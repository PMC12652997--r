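Package: ffpebench
Title: Benchmarking and Prioritizing Germline Variant Calls from FFPE Whole
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Post-calling analysis of germline variant call sets from matched
    fresh-frozen (FF) and formalin-fixed paraffin-embedded (FFPE) whole-genome
    sequencing. Constructs truth sets from the intersection of two variant
    callers, benchmarks query call sets against a truth set (precision,
    recall, F1, false-negative/false-positive rates, genotype concordance),
    summarises call sets (Ts/Tv, het/hom, del/ins, singletons, multiallelic
    sites), characterises single-nucleotide substitution spectra with Poisson
    standard errors to expose FFPE deamination artifacts, applies GATK-style
    hard filters, and prioritizes candidate variants for autosomal-recessive
    disease against a control cohort. A seeded synthetic VCF generator
    emulates the statistical structure of real call sets so that every stage
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
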