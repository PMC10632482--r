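Package: immunomet
Title: Immuno-Metabolic Profiling of Dendritic-Cell Vaccines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for immuno-metabolic analysis of dendritic-cell (DC)
    vaccine products and circulating myeloid cells. Implements per-cell
    SCENITH metabolic-dependence scoring from puromycin incorporation under
    metabolic inhibitors, single-cell glycolytic/mitochondrial quantile
    binning of oligomycin-treated cells, extracellular-flux (Seahorse)
    bioenergetic index derivation from kinetic OCR/ECAR traces, supernatant
    glucose/lactate flux and glucose-to-lactate conversion, IFN-gamma
    ELISPOT response calls, and outcome statistics (Kaplan-Meier, log-rank,
    maximally selected rank-statistic cutpoints, univariate Cox
    proportional hazards, normality-routed two-group tests, multiple-testing
    correction). A seeded synthetic-cohort generator emulates the data
    structure of a DC-vaccine trial so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
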