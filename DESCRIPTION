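Package: renyihet
Title: Numbers-Equivalent Heterogeneity Measures for Categorical and
    Non-Categorical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the heterogeneity of a system -- the degree to which
    it diverges from perfect conformity -- in units of numbers equivalent:
    the size of a hypothetical perfectly even categorical system with the
    same heterogeneity. Implements the Renyi heterogeneity (Hill number)
    family with alpha/beta/gamma decomposition and diversity profiles,
    classical categorical indices (Shannon entropy, Gini-Simpson, Simpson
    concentration, observed richness), Chao1 lower-bound richness
    estimation with bootstrap and analytic confidence intervals,
    combinatorial upper bounds on criteria-satisfying symptom
    presentations, Lorenz-curve inequality indices (Gini, Pietra),
    distance-based indices (Rao quadratic entropy, functional Hill
    numbers, convex-hull area, dendrogram branch-length functional
    diversity), and spectral numbers equivalent for time series. Ships
    seeded synthetic-data generators, tab-separated readers and writers,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, vegan
Config/testthat/edition: 3
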