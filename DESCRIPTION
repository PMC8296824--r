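Package: cgpdnet
Title: Chemical-Gene-Phenotype-Disease Tetramer Inference and Pesticide
    Action-Level Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs chemical-gene-phenotype-disease (CGPD) tetramers
    from five independently curated pairwise interaction sets in the
    Comparative Toxicogenomics Database (CTD) flat-file dialect, builds the
    tetramer-weighted bipartite chemical-by-gene network with weighted
    degree centrality, and summarizes gene connections per biological
    function with epilepsy-gene panel overlap.  A second analysis arm
    compares pesticide action levels for cannabis across jurisdictions
    (medians, ranges, fold-differences against reference tolerances) and
    tabulates qualifying-condition category coverage for medical-cannabis
    programs.  A synthetic-data generator emits CTD-like interaction
    tables with planted tetramers and decoys, action-level tables with
    planted statistics, and condition tables with planted coverage, each
    accompanied by machine-readable ground truth, so every pipeline stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
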