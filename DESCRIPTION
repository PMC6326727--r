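Package: coaggr
Title: Quantifying Combinatorial Cell Adhesion from Coaggregation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-colour cell coaggregation assays and
    targeted single-cell expression panels used to study combinatorial
    adhesion codes such as the delta-protocadherins. Implements the
    CoAggregation Index (the fraction of occupied grid squares of a
    two-channel aggregate image containing both colours) with behaviour
    classification, aggregate-size measurement with a minimum-cell filter,
    a constrained gamma-normal mixture model fitted by EM for per-cell
    on/off expression calls from targeted count panels, a Monte Carlo
    cell-binding network simulator of differential adhesion, mismatch-screen
    analytics (net mismatch scores, CoAg regression), and seeded synthetic
    data generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    withr,
    fitdistrplus,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
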