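Package: mitovar
Title: Filtering, Annotation and Gene-Level Enrichment of Mitochondrial
    DNA Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing of per-sample variant calls from targeted
    sequencing of the haploid mitochondrial genome: removal of
    heterozygous-looking calls and strand-imbalanced calls, aggregation
    into study-wide variants with carrier counts, annotation against a
    circular gene model (variant type, known-variant catalog status,
    conservation, codon and amino-acid change under the vertebrate
    mitochondrial genetic code, predictor concordance, homopolymer
    context), and per-gene global and weighted variant-enrichment rates
    with normality testing and percentile placement. Includes a
    synthetic-data generator with ground-truth labels for validating
    every stage, and a bundled set of reference study tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    VariantAnnotation,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
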