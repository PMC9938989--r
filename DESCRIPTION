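Package: riverseason
Title: Spatio-Temporal Microbiome Dynamics of a Wastewater-Impacted Urban River
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-year, monthly 16S amplicon surveys of an
    urban river system receiving treated wastewater. Implements baseline-anchored
    UniFrac beta-distance time series with winter interpolation, STL decomposition
    and Friedman seasonality inference; time-resolved site-pair permutation tests
    of a treatment-plant intervention; median-based bootstrap tests for fecal
    coliform and physicochemical shifts; a seasonal ASV log-ratio index; and a
    synthetic-study generator (counts, phylogeny, metadata, coliform and
    physicochemical series) that emulates the study design so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
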