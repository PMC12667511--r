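Package: hierlink
Title: Hierarchical Deterministic-Probabilistic Record Linkage for Health Registries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links person records across public-health registries that lack a
    shared unique identifier, using a 13-step hierarchical strategy that starts
    with deterministic matching on statistical linkage keys (name, mother's
    name, date of birth) and falls back to probabilistic matching with Jaro and
    Jaro-Winkler string similarity under per-step blocking. Includes an
    accuracy-evaluation harness (confusion matrices, sensitivity, specificity,
    predictive values with binomial confidence intervals), a synthetic
    Brazilian-style registry generator with configurable typographical
    corruption for benchmarking at known ground truth, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stringi,
    yaml,
    jsonlite,
    Rcpp,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
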