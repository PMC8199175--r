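Package: oncofetal
Title: Discovery of Oncofetal miRNAs from Multi-Cohort Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies oncofetal miRNAs - miRNAs expressed in fetal lung and
    lung adenocarcinoma but absent from adult non-neoplastic lung - from
    miRNA-by-sample read-count matrices across a discovery and a validation
    cohort. Provides reads-per-million normalization, a presence/absence
    expression-detection rule, dual-cohort differential expression with
    cohort-specific testing schemes, three-criterion oncofetal
    classification, genomic-cluster localization, a linear support vector
    machine panel scorer with ROC evaluation, Kaplan-Meier / log-rank
    survival stratification by expression positivity, and a synthetic
    two-cohort generator with planted miRNA classes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
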