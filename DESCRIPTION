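Package: ibrscape
Title: Isolation-by-Resistance Landscape Genetics from Suitability
    Models and Circuit Theory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A comparative landscape-genetics pipeline linking multilocus
    co-dominant genotypes to landscape structure. From presence records and
    environmental raster layers it fits penalised presence/background
    suitability models per landscape scenario, converts suitability into
    conductance surfaces, computes circuit-theoretic effective resistances
    between sampled populations, and compares the resulting resistance
    matrices against genetic differentiation (Weir-Cockerham F_ST and
    Jost's D_est) by AICc multimodel inference and multiple regression on
    distance matrices. Ships a synthetic-landscape and genotype generator
    so the full analysis is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    glmnet,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
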