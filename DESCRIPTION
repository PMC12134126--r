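Package: delatlas
Title: Spatial Domains and Differentially Expressed lncRNAs in the Mouse Gastrula
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying differentially
    expressed lncRNAs (DELs) across spatial domains of corn-plot structured
    gastrula transcriptomes: highly-variable-gene selection, hierarchical
    preliminary domains, pairwise Welch-t/fold-change calls, jackstraw-based
    principal-component significance, K-means final domains, and gene-group
    clustering by BIC-selected spherical K-means.  Companion stages cover
    weighted co-expression networks (soft threshold, topological overlap,
    module eigengenes, module-trait categories), a 4C-seq interaction by
    differential-expression candidate screen, and H3K27ac/H3K4me3 region
    classification.  A synthetic embryo generator with known ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
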