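Package: meltshift
Title: Thermal Shift Assay Melt-Curve Fitting and Hit Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end processing of high-throughput thermal shift assay
    (differential scanning fluorimetry) screens. Parses raw qPCR melt-curve
    exports, joins compound plate maps from SD files or SMILES CSVs, flags
    pathological wells (low signal, inverted shape, discontinuities), fits
    each melting curve to a five-parameter log-logistic model, derives the
    midpoint melting temperature, calls hits against DMSO control
    variability, and writes annotated SDF/CSV results, multi-sheet XLSX
    reports, and plate heatmaps. Includes a ground-truth-labelled plate
    simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    zip
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse
Config/testthat/edition: 3
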