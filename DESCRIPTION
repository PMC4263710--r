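Package: ontomap
Title: Ontogenic Expression Profiling of Coding and Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for developmental (ontogenic) RNA-seq time
    courses with matched coding and long non-coding RNA annotation. Merges a
    primary biotype-bearing gene annotation with a secondary lncRNA model set
    (keeping only non-overlapping models), filters expressed genes from a
    replicated multi-age FPKM matrix, tests differential expression across
    ages by one-way ANOVA with Benjamini-Hochberg correction, clusters
    differential genes into ontogenic stage patterns by average-linkage
    hierarchical clustering on correlation distance, computes inter-age
    similarity matrices, analyses expression correlation of nearest-neighbour
    coding/lncRNA gene pairs against a seeded random-pair null, selects
    concordant cis-candidate pairs, and runs hypergeometric gene-set
    enrichment. Includes a synthetic-data generator with planted ontogenic
    patterns and cis-coupled neighbour pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
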