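Package: sigrev
Title: Signature-Reversal Drug Repurposing from Transcriptomic Case-Control Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, self-contained pipeline for transcriptome-driven drug
    repurposing in case-control designs such as tumour versus normal tissue:
    negative-binomial differential expression on raw counts with
    median-of-ratios normalisation, direction-consistent intersection of two
    cohorts' differentially expressed gene (DEG) sets, hypergeometric
    over-representation analysis against user-supplied GMT collections,
    score-thresholded protein-protein interaction subnetworks with degree-based
    hub ranking, Kaplan-Meier / log-rank survival screening of hub genes after
    median-expression dichotomisation, and a bidirectional hypergeometric
    signature-reversal screen against a CREEDS-style drug-perturbation
    signature library. Ships a seeded synthetic-data generator that plants
    known DEGs, hubs, prognostic genes and reversal drugs so every stage is
    verifiable against ground truth without external databases.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
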