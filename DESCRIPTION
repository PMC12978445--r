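Package: riceideo
Title: Inverse Ideotype Design for Rainfed Rice
Version: 0.1.0
Authors@R:
    person("riceideo", "developers", email = "riceideo@example.org",
           role = c("aut", "cre"))
Description: An inverse-engineering pipeline for phenotype optimization of
    rainfed rice. Provides a surrogate process-based growth simulator exposing
    the eleven CERES-style genetic coefficients, replicated Morris
    elementary-effects screening summarised by a Relative Sensitivity Index,
    a genetic-algorithm ideotype optimizer driven by a combined harvest-index
    and water-use-efficiency fitness, multi-metric similarity ranking of field
    cultivars against optimized ideotypes, and synthetic weather, soil and
    cultivar-panel generators emulating the Casamance / Eastern Senegal
    environments so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
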