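Package: hydroprofiler
Title: Hydrogenase Activity Profiling of Shotgun Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Functional profiling of hydrogenase genes in shotgun
    metagenomes. Classifies short reads against an activity-annotated
    hydrogenase protein reference (uptake, evolving, bidirectional,
    bifurcating, sensory) with a translated six-frame seed-and-extend
    search, curates the reference with an in-silico knockout decoy
    procedure, quantifies and compares activity-category abundances
    between host conditions with zero-substituted, Bonferroni-corrected
    Mann-Whitney U statistics, and computes colonization-fitness
    statistics (CFU estimation, limit-of-detection handling, competitive
    index, geometric-mean summaries, comparative-Ct expression). Includes
    a seeded synthetic-data generator producing reference databases,
    genomes with embedded hydrogenase genes, knockout genome variants,
    condition-stratified communities and error-bearing paired-end reads
    with ground-truth provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
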