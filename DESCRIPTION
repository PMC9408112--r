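Package: couplecoord
Title: Supply-Demand Coupling Coordination Analysis for Regional Service Resources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how well the supply of a regional service
    system keeps pace with demand for it, developed around elderly-care
    service resources across the 31 mainland Chinese province-level regions.
    Implements per-year min-max indicator standardization with orientation
    handling, entropy weighting of indicators, linear-weighted subsystem
    composite scores, the coupling degree and coupling coordination degree
    with a ten-level classification, global Moran's I spatial autocorrelation
    with permutation inference, and sliding-window neural-network forecasting
    of indicator series. Includes a synthetic panel generator with known
    ground truth for validating every stage, a queen-contiguity adjacency
    fixture for mainland China, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
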