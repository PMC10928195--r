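Package: overyieldN
Title: Biodiversity-Effect Partitioning Under Nitrogen Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how nitrogen enrichment alters grassland
    overyielding. Implements the Loreau-Hector additive partition of net
    biodiversity effects into complementarity and selection effects from
    plot-level species biomass records, cumulative nitrogen exposure
    accounting (experimental addition plus atmospheric deposition), a
    hierarchy of linear mixed-effects models with first-order autoregressive
    temporal correlation and AIC-based model comparison, and a synthetic
    multi-study community-experiment generator with exact, invertible
    complementarity/selection targets for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
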