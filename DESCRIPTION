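Package: standres
Title: Tree- and Stand-Level Drought Response Analysis for Mixed Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for quantifying drought responses of trees
    and forest stands in long-term thinning experiments. Converts tree-ring
    width series (Tucson format) to basal area increment with bark correction
    and backwards diameter reconstruction, computes the Standardized
    Precipitation-Evapotranspiration Index (SPEI) from monthly climate with
    Hargreaves potential evapotranspiration, derives distance-dependent
    neighborhood competition and stand-structure covariates from mapped
    inventories, calculates Lloret resistance, recovery and resilience
    indices around drought events, and fits linear mixed-effects models with
    all-subsets AICc selection, Nakagawa R-squared and variance-component
    effect sizes. Includes a synthetic-data generator with known ground-truth
    effect sizes so the whole pipeline is testable without restricted field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    vegan,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
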