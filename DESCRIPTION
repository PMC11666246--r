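Package: dnalim
Title: Analysis of DNA-Limited Growth in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how genome concentration limits bacterial cell
    growth. Implements single-cell growth-rate kinetics from segmentation mask
    time series, single-molecule tracking with apparent-diffusion-coefficient
    classification by a Gaussian mixture model, fluorescent spot and nucleoid
    detection with ploidy classification, proteome and transcriptome size-scaling
    slopes from TMT peptide and TPM tables, matched-population bootstrapped
    concentration ratios, and ordinary-differential-equation models of
    DNA-limited transcription and translation. A synthetic-data module generates
    inputs with the statistical structure each stage assumes, so the whole
    pipeline is exercisable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    mclust,
    minpack.lm,
    EBImage,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
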