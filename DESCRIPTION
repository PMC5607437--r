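Package: searchlex
Title: Lexical Analysis of Internet Search Queries as a Marker of
    Cognitive Function in Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating everyday Internet-search language to
    cognitive function in older adults. Implements a query-log cleaning
    pipeline (ASCII normalization, corpus-based spell correction,
    dictionary-validated lemmatization), per-subject lexical metrics
    (unique terms per search, mean word length, inverse-frequency term
    obscurity), composite neuropsychological z-scores normed on a
    cognitively intact reference cohort, covariate-adjusted directional
    linear models with variance-inflation diagnostics, term
    co-occurrence network construction and export, and a calibrated
    synthetic cohort generator for validation and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    xml2,
    car
Config/testthat/edition: 3
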