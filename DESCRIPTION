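Package: reirrad
Title: Dose Accumulation and Outcome Analysis for CNS Re-Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-course radiotherapy of recurrent
    malignant glioma: dose-volume histogram (DVH) handling with
    cumulative/differential conversion and digitised-hardcopy ingestion,
    equivalent uniform dose (EUD) computation for organs at risk and tumour
    targets, conservative cumulative-dose estimation across a primary and a
    re-irradiation course with a normal-tissue recovery correction,
    equivalent-sphere tumour geometry, Kaplan-Meier / log-rank / univariate
    Cox survival analyses, and a fully synthetic cohort generator used as
    the test substrate for the whole pipeline.
License: MIT
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
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
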