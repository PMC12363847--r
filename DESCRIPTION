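Package: grnarch
Title: Regulatory Network Topology and the Genetic Architecture of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates gene regulatory networks as random directed acyclic
    graphs (reparameterized planted-partition and modular acyclic scale-free
    generators), propagates cis-acting genetic variation through a linear
    structural equation model of expression, and decomposes each gene's
    genetic variance into cis and trans components exactly from the
    total-effects matrix L = (I - G)^-1. Includes closed-form expected
    cis-fractions for feed-forward (triangle) and bi-parallel (diamond)
    motifs with an exhaustive sign-enumeration oracle, motif counting,
    distance-resolved heritability decompositions, Kolmogorov-Smirnov
    matching of simulated cis-fraction distributions against per-gene
    heritability tables, residualization and mediation analyses over
    parameter sweeps, and a synthetic heritability-table generator.
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
    igraph,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
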