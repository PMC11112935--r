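Package: tilspot
Title: Spatial Hot/Cold-Spot Profiling of Tumor-Infiltrating Lymphocytes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial immune microenvironment of tumors from
    double-immunohistochemistry cell tables. Implements whole-tumor-area
    (WTA) densities of CCR8+Foxp3+ regulatory T cells and GzmB+CD8+
    cytotoxic T cells, density-map-based Hot/Cold-Spot field selection
    (region-of-interest protocol), per-field immune metrics, the GzmB/CCR8
    prognostic ratio, clinicopathological association tests, and
    Kaplan-Meier/Cox survival analysis of progression-free survival.
    Includes a marked-point-process cohort simulator that emulates
    spatially clustered lymphocyte infiltration, local Treg-mediated
    suppression of granzyme-B expression, and proportional-hazards
    outcomes, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
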