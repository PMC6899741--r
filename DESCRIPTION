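Package: magscore
Title: Module Completion Scoring and Functional Profiling of
    Metagenome-Assembled Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-resolved functional profiling of microbial communities
    from metagenomes and metatranscriptomes. Parses KEGG-style boolean
    module definitions, scores metabolic module completion (MCS) of
    metagenome-assembled genomes (MAGs) from KO annotations, normalizes
    key-gene abundances by single-copy marker genes (metagenomes) or
    library size (metatranscriptomes), normalizes and z-scores per-MAG
    coverage profiles, clusters MAGs and samples by expression pattern
    (Euclidean distance, Ward linkage), and tests per-module enrichment
    between MAG groups with the Mann-Whitney U test. Includes a seeded
    synthetic-data generator that plants ground-truth module completion,
    block expression structure and group-wise completion shifts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
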