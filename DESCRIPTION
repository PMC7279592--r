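Package: phylosat
Title: Substitution-Saturation Aware Gene Benchmarking for Mitogenome
    Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to rank mitochondrial genes by phylogenetic
    informativeness. Provides per-gene substitution-saturation profiling
    via the correlation of transition and transversion proportions,
    closed-form evolutionary distances (JC69, K2P, TN93, log-det) with
    gamma and invariant-site corrections, neighbor-joining, maximum
    parsimony and maximum likelihood tree inference with nonparametric
    bootstrap and consensus trees, a support-thresholded node-congruence
    score against a whole-mitogenome reference topology, and a
    ground-truth sequence simulator (Yule species trees, GTR+G+I gene
    models, graded rate multipliers) so every stage of the pipeline can
    be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
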