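Package: agrisuit
Title: AHP-Weighted Multi-Criteria Land Suitability Mapping for Coffee
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for agro-ecological land-suitability analysis of coffee
    plantations: Analytic Hierarchy Process (AHP) priority weights with
    consistency diagnostics from pairwise comparison matrices, rule-based
    reclassification of thematic raster layers into ordinal suitability
    scores, inverse-distance-weighted climate surfaces, slope/aspect and
    Euclidean-distance derivations, SAR backscatter thresholding for coffee
    cover mapping, weighted-overlay suitability scoring with area tabulation
    and accuracy assessment, and a seeded synthetic landscape generator for
    fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
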