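Package: ircube
Title: Processing and Quality Control of FTIR Hyperspectral Maps of Stratum Corneum
Version: 0.1.0
Authors@R:
    person("Ondrej", "Novak", email = "ondrej.novak@example.org",
           role = c("aut", "cre"))
Description: Tools for processing hyperspectral absorbance cubes from
    focal-plane-array FTIR microspectroscopy of stratum corneum samples:
    iterative polynomial baseline correction, area and Amide II
    normalization, band intensity/integral/ratio chemical mapping,
    outlier-pixel removal by Tukey-fence histogram thresholding and by
    PCA score distance, and the dispersion, retention and compactness
    metrics used to compare those strategies. Includes a seeded
    simulator of stratum-corneum-like maps with ground-truth artifact
    masks for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
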