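Package: allelochoice
Title: Allele-Specific Analysis of Clonal V-Segment Choice in Hybrid Pre-B Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying allelic choice of immunoglobulin kappa V
    segments in F1 hybrid (C57BL/6 x CAST) pre-B-cell clones. Implements
    SNP-based tagging of reads to their parental genome, strand-aware
    assignment of read pairs to V segments, allelic-ratio computation,
    monoallelic calling by an exact binomial test with false-discovery-rate
    correction, fold-change and replicate-consistency rules, a stochastic
    per-allele Bernoulli activation model with maximum-likelihood estimation
    and goodness-of-fit, clonal-stability profiling by principal components
    and hierarchical clustering, and rearrangement-repertoire normalization
    and correlation with germline non-coding transcription. A synthetic
    hybrid-clone data generator with negative-binomial count noise emulates
    the statistical structure of the assays so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
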