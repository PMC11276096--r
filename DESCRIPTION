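Package: pomochem
Title: Chemometric Analysis of Apple Cultivar Composition and Antioxidant
    Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for targeted metabolite profiling of fruit cultivars:
    tidy handling of replicate-level analyte tables (polyphenols, organic
    acids, sugars) with structural non-detects, antioxidant assay
    mathematics (DPPH percent inhibition and IC50 estimation, gallic-acid
    and ascorbic-acid equivalent calibration), correlation-matrix principal
    component analysis with signed per-variable contributions, Pearson
    correlation screening with t-based significance, a feed-forward
    multilayer perceptron trained by multi-start BFGS, and Yoon's
    connection-weight sensitivity analysis for interpreting trained
    networks.  Ships transcriptions of a published seven-cultivar apple
    composition study as worked-example fixtures, plus seeded synthetic-data
    generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
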