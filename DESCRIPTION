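Package: grscore
Title: Genetic Risk Scores for Psoriasis Case-Control and Family Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of multi-locus genetic risk scores
    (GRS) from small SNP panels, modelled on the ten-locus psoriasis panel.
    Computes count and log-odds-weighted scores, exact score distributions
    under Hardy-Weinberg equilibrium, liability-threshold estimates of the
    genetic variance explained per SNP, per-SNP additive association and
    quartile odds-ratio models, ROC/AUC discrimination with the DeLong
    paired comparison, within-family score summaries, and a synthetic
    case-control and nuclear-family genotype generator for end-to-end
    testing of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr,
    pROC,
    vcfR,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
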