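Package: nammap
Title: Linkage Maps, Consensus Maps and Genome-Diversity Statistics for
    NAM Panels of Selfed Recombinant Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds genetic linkage maps from biparental populations of
    single-seed-descent recombinant inbred lines (F4-F6 or fully inbred),
    merges them into per-chromosome consensus maps by order-constrained
    linear programming, and derives diversity statistics across a nested
    association mapping (NAM) panel: marker-distance ratios with Tukey-fence
    outliers, marker-order incongruence, segregation-distortion scans on
    HMM-imputed genotypes, translocation calls from chromosome-assignment
    conflicts and inter-chromosome recombination-fraction LOD signals, and
    QTL mapping of per-line crossover counts.  Includes a meiosis-level
    simulator of selfed-RIL NAM panels with known truth (structural
    variants, distortion loci, crossover modifiers) so the whole pipeline
    is testable without external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
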