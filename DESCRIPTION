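Package: venomdelta
Title: Comparative Venom-Gland Transcriptomics and Proteomics for Two-Species Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative venom-gland analysis of two closely related
    snake species sampled at small n: compositional (centered log-ratio)
    normalization of TPM expression, differential-expression calling of toxins
    against a nontoxin-derived null band around an orthogonal best-fit line,
    reciprocal-best-hit orthology with codon-aware alignment, pairwise dN/dS by
    Nei-Gojobori counting with Jukes-Cantor correction and dS-range filtering,
    weighted coexpression module detection, genome-free miRNA quantification
    with seed-site target scanning on toxin 3'UTRs, spectral-count proteome
    integration with translation-efficiency estimation, and a fully specified
    synthetic two-species cohort generator with recorded ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    mclust,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
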