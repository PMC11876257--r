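Package: quantTCF
Title: Computational Tumor Cellular Fraction and Purity-Corrected Copy-Number Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the tumor cellular fraction (TCF) of H&E-stained tissue
    regions by detecting and classifying nuclei inside a pen-marked region of
    interest, applies the molecular-adequacy gate (>= 100 viable tumor cells
    and TCF >= 20 percent), propagates the revised cellularity into
    purity-corrected copy-number calls with a five-of-six confidence gate, and
    quantifies observer agreement on TCF scores with the quadratic weighted
    kappa. Includes a synthetic H&E scene generator with per-nucleus ground
    truth, simulated observer ratings, and synthetic copy-number tables so the
    whole pipeline is testable without slide data, plus QuPath-dialect GeoJSON
    import/export of detections and classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    randomForest,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
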