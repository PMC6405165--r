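Package: embryoscreen
Title: Semi-Automated Analysis of 96-Well Time-Lapse Screens of Fish Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput 96-well time-lapse imaging of
    fish embryos: randomized plate design, Otsu-based embryo segmentation with
    dual-channel masking, ratiometric fluorescent-protein intensity traces
    normalized to an injection control, quality-control filtering of dead or
    non-developing wells, plate fusion via internal controls, condition ranking,
    cross-species intensity renormalization, a frame-differencing movement index
    for anaesthesia assays, startle-response scoring, codon adaptation index
    scoring and codon-usage-driven back-translation, plus a ground-truthed
    synthetic plate-image generator against which every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
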