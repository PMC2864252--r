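Package: decaytiming
Title: mRNA Decay Rates and the Temporal Order of Gene Induction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how mRNA degradation rates shape the
    kinetics of gene induction and suppression in time-course expression
    data. Implements the first-order kinetic model of transcript abundance
    (closed-form transitions, pulse simulation, fold-induction timing, and
    a transcription-shutoff half-life bound), first-crossing kinetic
    clustering of expression time courses, rank-sum association tests
    between response time and half-life or gene length, cross-dataset
    core-set extraction, 3'-UTR k-mer and category enrichment with FDR
    control, and a synthetic-data generator with known ground truth for
    end-to-end validation.
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
    utils,
    Biostrings
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
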