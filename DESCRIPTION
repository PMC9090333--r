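Package: lineadapt
Title: Single-Cell Lineage Analysis of Physiological Adaptation to
    Resistance-Gene Deletion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of mother-machine single-cell lineage
    data from experiments in which an antibiotic-resistance gene is deleted
    in individual Escherichia coli cells under chloramphenicol exposure.
    Provides a seeded stochastic generator of post-segmentation lineage
    tables (exponential elongation with sizer division, fluorescence
    production and dilution by growth, light-induced deletion,
    condition-dependent growth-halt versus growth-restoration dynamics,
    dual ribosomal-reporter ratio dynamics); per-lineage feature extraction
    (windowed elongation rates, generation tables, normalized fluorescence,
    subunit ratios, the expected dilution curve); fate classification by
    threshold rules validated with dynamic-time-warping hierarchical
    clustering; lineage-resampling bootstrap median bands and related
    population statistics; and the closed-form ancestry and limiting-dilution
    Poisson probability models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
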