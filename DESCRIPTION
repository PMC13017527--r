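Package: predinfo
Title: Predictive Information of Discrete Meaning-Form Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact computation of the predictive information (excess entropy)
    of the stationary symbol process induced by a discrete code mapping
    meanings to strings, together with simulation experiments showing that
    minimizing predictive information yields systematic, local and
    hierarchically well-nested codes, and attested-versus-counterfactual
    baseline analyses for phonotactics, morphology, adjective-noun syntax,
    noun-phrase word order and lexical semantic features. Includes seeded
    synthetic-data generators emulating paradigm tables, phonemic lexicons,
    phrase-count tables and binary semantic-feature norms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
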