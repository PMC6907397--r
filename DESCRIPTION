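Package: wgdmap
Title: Whole-Genome Duplication Detection and Linkage-Map Reconciliation
    of Chromosome-Scale Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconciling proximity-guided (Hi-C style) chromosome-scale
    scaffold orderings with RAD-seq linkage maps, including detection and splitting
    of chimeric scaffolds at single-N junctions and correction of large-scale
    inversions, and for detecting and temporally placing shared whole-genome
    duplications from syntenic-block structure and Ks age distributions. Implements
    pseudo-testcross linkage analysis with Haldane map distances, DAGChainer-style
    collinear block chaining with syntenic depth and coverage, NG86 Ks estimation
    with gene-family deduplication, SiZer significance maps for Ks peak detection,
    and Gaussian mixture fitting with BIC model selection. A synthetic-data module
    generates genomes with planted duplications, assembly errors, and simulated
    crosses so every stage is verifiable against known truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    stats,
    utils,
    tools,
    yaml,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
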