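Package: arsbind
Title: Binding Affinity Analytics for Protein-Functionalized Biosilica
    Arsenic Adsorbents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of protein-As(III) binding on
    protein-functionalized biosilica particles. Converts between mass,
    particle-count and molar descriptions of adsorbent suspensions; fits
    pseudo-first- and pseudo-second-order adsorption kinetics by their
    classical linearizations; performs solid-phase Scatchard analysis
    (association constant and per-particle site number from equilibrium
    isotherms, with automatic linear-segment selection and delta-method
    uncertainties); infers the affinity of a free protein from competition
    against an immobilized reference via a mass-balance linearization;
    and scores immobilization loading, conjugate stability and As(III)
    selectivity under competing heavy metals. A seeded forward simulator
    generates every experiment type from exact 1:1 Langmuir and
    two-receptor competitive equilibria, serving both as a testbed for
    parameter recovery and as a source of worked datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
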