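Package: intersexpr
Title: Expression-Pattern Classification of Intersex Backcross Mosquitoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for classifying sex-, species- and
    tissue-associated gene expression from bulk RNA-seq counts and profiling
    its misregulation in intersexual hybrid backcross mosquitoes. Provides a
    negative-binomial exact test for two-group differential expression with
    moment-based shrinkage dispersion estimation, FPKM quantification, a
    threshold decision tree assigning genes to low / unbiased / biased /
    specific categories, rule-based expression clusters and sex-by-tissue
    gene groups, a five-comparison intersex pattern classifier
    (no change / up / down / other), contingency-table association tests
    (Pearson chi-square and likelihood-ratio G) for pupal-versus-adult
    feminization phenotypes, and a negative-binomial count simulator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    optparse,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
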