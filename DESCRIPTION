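Package: devindex
Title: Evolutionary Transcriptome Indexes Across Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing developmental constraints on genome evolution
    from bulk developmental transcriptomes. Computes per-stage transcriptome
    evolutionary indexes (expression-weighted means of gene-level evolutionary
    parameters such as dN/dS under purifying selection, phyletic age, paralog
    number, and protein connectivity), bootstrap confidence intervals, and a
    one-sided early-versus-middle permutation test that distinguishes the
    developmental hourglass from the early-conservation model. Also provides
    temporal-pleiotropy profiling, the Tau tissue-specificity index with
    testis-specific gene filtering, retrogene expression trend analysis, a
    connectivity-duplicability analysis, and a synthetic developmental
    transcriptome generator with controlled coupling between expression timing
    and evolutionary parameters for end-to-end validation.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
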